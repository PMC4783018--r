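# Jointly permute rows and columns of a square matrix.
permute_dist <- function(m, perm) m[perm, perm]

mantel_r <- function(A, B) {
  a <- lower_tri_vec(A); b <- lower_tri_vec(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a distance matrix's lower triangle")
  stats::cor(a, b)
}

new_mantel_result <- function(r, p, n_perm, kind, controlled, seed) {
  structure(list(r = r, p = p, n_perm = n_perm, kind = kind,
                 controlled = controlled, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel%s: r = %.4f, p = %.4g (%d permutations)\n",
              if (x$kind == "partial") "Partial" else "Simple",
              if (x$kind == "partial") sprintf(" (controlling %s)", x$controlled)
              else "", x$r, x$p, x$n_perm))
  invisible(x)
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two distance matrices, with
#' significance from joint row/column permutation of the second matrix:
#' p = (1 + #permuted statistics at least as extreme) / (1 + n_perm).
#'
#' @param A,B `dist_matrix` objects with identical labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed; required for reproducible p-values.
#' @param alternative `"two.sided"` (default, on |r|) or `"greater"`.
#' @return a `mantel_result` with elements `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(A, B, n_perm = 9999, seed, alternative = c("two.sided",
                                                              "greater")) {
  alternative <- match.arg(alternative)
  check_same_labels(A, B)
  n <- nrow(A)
  if (n < 4) stop("need at least 4 individuals")
  if (n_perm < 99) stop("n_perm must be at least 99")
  r_obs <- mantel_r(A, B)
  a <- lower_tri_vec(A)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_k <- stats::cor(a, lower_tri_vec(permute_dist(B, perm)))
    hit <- if (alternative == "two.sided") abs(r_k) >= abs(r_obs) - 1e-12
           else r_k >= r_obs - 1e-12
    exceed <- exceed + hit
  }
  new_mantel_result(r_obs, (1 + exceed) / (1 + n_perm), n_perm, "simple",
                    NULL, seed)
}

# residuals of the lower triangle of A regressed on that of C
tri_residuals <- function(A, C) {
  a <- lower_tri_vec(A); cc <- lower_tri_vec(C)
  stats::residuals(stats::lm(a ~ cc))
}

# rebuild a symmetric zero-diagonal matrix from a lower-triangle vector
tri_to_matrix <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Partial Mantel permutation test
#'
#' Correlation between A and B after removing the (triangle-wise) linear
#' effect of a third matrix C from both; used here to compensate for
#' geographic distance when judging resistance surfaces. Significance by
#' permutation of the residuals of B (residual-permutation method): the
#' residual matrix of B|C is jointly row/column permuted each iteration.
#'
#' @inheritParams mantel
#' @param C the controlled `dist_matrix` (e.g. geographic distance).
#' @return a `mantel_result` with `kind = "partial"`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 9999, seed,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  check_same_labels(A, B, C)
  n <- nrow(A)
  if (n < 4) stop("need at least 4 individuals")
  rbc <- stats::cor(lower_tri_vec(B), lower_tri_vec(C))
  if (!is.finite(rbc) || abs(rbc) > 1 - 1e-10)
    stop("confounded control: C is collinear with B")
  res_a <- tri_residuals(A, C)
  res_b <- tri_residuals(B, C)
  if (stats::sd(res_a) == 0 || stats::sd(res_b) == 0)
    stop("zero residual variance; partial correlation undefined")
  r_obs <- stats::cor(res_a, res_b)
  res_b_mat <- tri_to_matrix(res_b, n)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_k <- stats::cor(res_a, lower_tri_vec(permute_dist(res_b_mat, perm)))
    hit <- if (alternative == "two.sided") abs(r_k) >= abs(r_obs) - 1e-12
           else r_k >= r_obs - 1e-12
    exceed <- exceed + hit
  }
  new_mantel_result(r_obs, (1 + exceed) / (1 + n_perm), n_perm, "partial",
                    attr(C, "kind") %||% "C", seed)
}
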