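#' Genotype table
#'
#' Diploid microsatellite genotypes for georeferenced individuals. Allele
#' calls are stored as an `n x L x 2` integer array (repeat counts or allele
#' codes); a missing call is `NA` in both slots of its locus.
#'
#' @param individuals character vector of unique individual labels.
#' @param loci character vector of locus labels.
#' @param calls integer array `n x L x 2`; both slots `NA` for missing calls.
#' @param coords data.frame with columns `x`, `y` (projected metres), one row
#'   per individual.
#' @param area_tag optional per-individual study-area label.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, calls, coords, area_tag = NULL) {
  n <- length(individuals)
  if (n < 2) stop("need at least 2 individuals")
  if (anyDuplicated(individuals))
    stop(sprintf("duplicate individual label(s): %s",
                 paste(unique(individuals[duplicated(individuals)]),
                       collapse = ", ")))
  stopifnot(length(dim(calls)) == 3, dim(calls)[1] == n,
            dim(calls)[2] == length(loci), dim(calls)[3] == 2)
  half <- is.na(calls[, , 1, drop = FALSE]) != is.na(calls[, , 2, drop = FALSE])
  if (any(half)) stop("half-missing calls: each call needs 2 alleles or none")
  if (nrow(coords) != n || !all(c("x", "y") %in% names(coords)))
    stop("coords must have one row per individual with columns x, y")
  if (any(!is.finite(coords$x)) || any(!is.finite(coords$y))) {
    bad <- individuals[!is.finite(coords$x) | !is.finite(coords$y)]
    stop(sprintf("individual(s) missing coordinates: %s",
                 paste(bad, collapse = ", ")))
  }
  dimnames(calls) <- list(individuals, loci, NULL)
  structure(list(individuals = individuals, loci = loci, calls = calls,
                 coords = data.frame(x = coords$x, y = coords$y,
                                     row.names = individuals),
                 area_tag = area_tag),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci, %d missing calls\n",
              length(x$individuals), length(x$loci),
              sum(is.na(x$calls[, , 1]))))
  invisible(x)
}

#' Read genotypes from GenePop text plus a coordinate table
#'
#' Supports the GenePop dialect with 2- or 3-digit allele codes concatenated
#' per locus (`0404`, `092095`); `0000`/`000000` is a missing call. All pops
#' are read; the pop an individual belongs to becomes its `area_tag`.
#'
#' @param genepop_path path to a GenePop file.
#' @param coords a data.frame with columns `id`, `x`, `y` (and optionally
#'   `area`), or a path to a CSV with those columns. Joined on individual
#'   label.
#' @return a `genotype_table`.
#' @export
read_genepop <- function(genepop_path, coords) {
  lines <- readLines(genepop_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("GenePop file too short")
  body <- lines[-1]                       # first line is the title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'pop' line found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(0); pops <- integer(0); rows <- list()
  pop_no <- 0L
  for (ln in body[-seq_len(pop_idx[1] - 1)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L; next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop(sprintf("malformed GenePop line: '%s'", ln))
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop(sprintf("individual '%s': %d genotypes for %d loci",
                   id, length(codes), length(loci)))
    w <- unique(nchar(codes))
    if (length(w) != 1 || !w %in% c(4L, 6L))
      stop(sprintf("individual '%s': allele codes must be 2 or 3 digits (got widths %s)",
                   id, paste(w, collapse = ",")))
    half <- w / 2
    a1 <- as.integer(substr(codes, 1, half))
    a2 <- as.integer(substr(codes, half + 1, w))
    a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    ids <- c(ids, id); pops <- c(pops, pop_no)
    rows[[length(rows) + 1L]] <- cbind(a1, a2)
  }
  n <- length(ids)
  calls <- array(NA_integer_, c(n, length(loci), 2))
  for (i in seq_len(n)) calls[i, , ] <- rows[[i]]
  if (is.character(coords)) coords <- utils::read.csv(coords)
  if (!all(c("id", "x", "y") %in% names(coords)))
    stop("coordinate table needs columns id, x, y")
  m <- match(ids, coords$id)
  if (anyNA(m))
    stop(sprintf("individual(s) missing coordinates: %s",
                 paste(ids[is.na(m)], collapse = ", ")))
  area <- if ("area" %in% names(coords)) coords$area[m] else
    paste0("pop", pops)
  genotype_table(ids, loci, calls,
                 data.frame(x = coords$x[m], y = coords$y[m]),
                 area_tag = area)
}

#' Write genotypes as GenePop text (one pop per area tag)
#'
#' @param g a `genotype_table`.
#' @param path output path.
#' @param title first line of the file.
#' @return `path`, invisibly. Round-trips losslessly through [read_genepop()].
#' @export
write_genepop <- function(g, path, title = "landres genotypes") {
  width <- if (max(g$calls, na.rm = TRUE) > 99) 3L else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", width, "d%0", width, "d"), a[, 1], a[, 2])
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  areas <- g$area_tag %||% rep("all", length(g$individuals))
  for (ar in unique(areas)) {
    writeLines("pop", con)
    for (i in which(areas == ar)) {
      codes <- fmt(matrix(g$calls[i, , ], ncol = 2))
      writeLines(sprintf("%s, %s", g$individuals[i],
                         paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Construct a labeled distance matrix
#'
#' Wraps a square symmetric matrix as a typed pairwise distance matrix, the
#' carrier used by every statistical routine in the package.
#'
#' @param values square numeric matrix; must be symmetric (within 1e-8) and
#'   is given a zero diagonal.
#' @param labels individual labels (default: rownames of `values`).
#' @param kind one of `"genetic_a"`, `"genetic_dps"`, `"geographic"`,
#'   `"effective"`.
#' @return a `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        kind = c("genetic_a", "genetic_dps", "geographic",
                                 "effective")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  if (is.null(labels)) labels <- sprintf("i%03d", seq_len(nrow(values)))
  if (kind == "genetic_dps" && any(values < -1e-12 | values > 1 + 1e-12))
    stop("Dps values must lie in [0, 1]")
  if (kind %in% c("geographic", "effective") && any(values < -1e-12, na.rm = TRUE))
    stop(sprintf("%s distances must be non-negative", kind))
  new_dist_matrix((values + t(values)) / 2, labels, kind)
}

#' Read a labeled distance matrix from CSV
#'
#' Counterpart of [write_dist_csv()]: first column (or row names) holds the
#' individual labels.
#'
#' @param path CSV file path.
#' @param kind distance kind, as in [dist_matrix()].
#' @return a `dist_matrix`.
#' @export
read_dist_csv <- function(path, kind = "effective") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(df), rownames(df), kind)
}

new_dist_matrix <- function(values, labels,
                            kind = c("genetic_a", "genetic_dps", "geographic",
                                     "effective")) {
  kind <- match.arg(kind)
  dimnames(values) <- list(labels, labels)
  diag(values) <- 0
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> kind=%s, %d individuals\n", attr(x, "kind"),
              nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

dist_labels <- function(d) rownames(d)

# lower-triangle vector in a fixed (column-major) order
lower_tri_vec <- function(m) m[lower.tri(m)]

check_same_labels <- function(...) {
  ms <- list(...)
  l0 <- dist_labels(ms[[1]])
  for (m in ms[-1])
    if (!identical(dist_labels(m), l0))
      stop("distance matrices have mismatched individual labels")
  invisible(l0)
}

#' Proportion-of-shared-alleles distance (Dps)
#'
#' For each pair, 1 minus the proportion of alleles shared across co-typed
#' loci: shared alleles are counted with multiplicity (0, 1 or 2 per locus)
#' and divided by twice the number of loci typed in both individuals. Loci
#' missing in either member of a pair are excluded for that pair.
#'
#' @param g a `genotype_table`.
#' @return a `dist_matrix` of kind `genetic_dps`, values in \[0, 1\].
#' @export
dps_matrix <- function(g) {
  n <- length(g$individuals); L <- length(g$loci)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- 0L; typed <- 0L
    for (l in seq_len(L)) {
      gi <- g$calls[i, l, ]; gj <- g$calls[j, l, ]
      if (anyNA(gi) || anyNA(gj)) next
      typed <- typed + 1L
      ti <- table(gi); tj <- table(gj)
      common <- intersect(names(ti), names(tj))
      shared <- shared + sum(pmin(ti[common], tj[common]))
    }
    if (typed == 0L)
      stop(sprintf("pair (%s, %s) has no co-typed locus",
                   g$individuals[i], g$individuals[j]))
    d[i, j] <- d[j, i] <- 1 - shared / (2 * typed)
  }
  new_dist_matrix(d, g$individuals, "genetic_dps")
}

#' Rousset's a between-individual genetic distance
#'
#' The between-individual analogue of F/(1-F): per locus, Qw is the
#' dataset-average probability of allelic identity within individuals and
#' Qb(i,j) the mean identity over the four inter-individual gene comparisons;
#' the multilocus statistic is the ratio of sums
#' a(i,j) = sum_l (Qw_l - Qb_l(i,j)) / sum_l (1 - Qw_l), restricted for each
#' pair to its co-typed loci. Values may be negative.
#'
#' @param g a `genotype_table`.
#' @return a `dist_matrix` of kind `genetic_a`.
#' @export
rousset_a_matrix <- function(g) {
  n <- length(g$individuals); L <- length(g$loci)
  qw <- vapply(seq_len(L), function(l) {
    a <- g$calls[, l, , drop = TRUE]
    ok <- !is.na(a[, 1])
    if (!any(ok)) return(NA_real_)
    mean(a[ok, 1] == a[ok, 2])
  }, numeric(1))
  if (all(is.na(qw) | qw >= 1 - 1e-12))
    stop("no polymorphism: every locus is monomorphic within individuals")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0; typed <- 0L
    for (l in seq_len(L)) {
      gi <- g$calls[i, l, ]; gj <- g$calls[j, l, ]
      if (anyNA(gi) || anyNA(gj) || is.na(qw[l])) next
      typed <- typed + 1L
      qb <- mean(outer(gi, gj, "=="))
      num <- num + (qw[l] - qb)
      den <- den + (1 - qw[l])
    }
    if (typed == 0L)
      stop(sprintf("pair (%s, %s) has no co-typed locus",
                   g$individuals[i], g$individuals[j]))
    if (den <= 0)
      stop("no polymorphism among the loci co-typed for a pair")
    d[i, j] <- d[j, i] <- num / den
  }
  new_dist_matrix(d, g$individuals, "genetic_a")
}

#' Euclidean geographic distance matrix
#'
#' Straight-line distances (m) between sampling locations.
#' @param g a `genotype_table`.
#' @return a `dist_matrix` of kind `geographic`.
#' @export
euclidean_matrix <- function(g) {
  d <- as.matrix(stats::dist(g$coords[, c("x", "y")]))
  new_dist_matrix(d, g$individuals, "geographic")
}

#' Write a distance matrix as labeled CSV
#' @param d a `dist_matrix`.
#' @param path output path.
#' @export
write_dist_csv <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path, row.names = TRUE)
  invisible(path)
}
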