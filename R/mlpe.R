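# Maximum-likelihood population effects (MLPE) regression of pairwise
# genetic distance on effective distance. Observations are unordered pairs
# (i, j); two observations that share exactly one individual have
# correlation rho, so with Z the N x n pair-to-individual incidence matrix
# (two 1s per row) the covariance is
#   V = sigma_e^2 (I + gamma Z Z'),  gamma = rho / (1 - 2 rho),
# because ZZ' has diagonal 2 and off-diagonal 1 exactly on pairs sharing an
# individual. The likelihood is profiled over gamma with the Woodbury
# identity and the matrix determinant lemma, so each evaluation costs
# O(N n + n^3) with n = number of individuals, never O(N^3).

pair_index <- function(labels) {
  n <- length(labels)
  ut <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  # lower.tri order matches lower_tri_vec()
  data.frame(i = ut[, 2], j = ut[, 1])
}

mlpe_profile <- function(gamma, y, X, Z) {
  N <- length(y); n <- ncol(Z)
  M <- diag(n) + gamma * crossprod(Z)          # I + gamma Z'Z
  cM <- chol(M)
  # A u = (I - gamma Z M^-1 Z') u  (V^{-1} up to 1/sigma_e^2)
  Au <- function(u) u - gamma * (Z %*% backsolve(cM, forwardsolve(t(cM), crossprod(Z, u))))
  AX <- Au(X); Ay <- Au(y)
  XtAX <- crossprod(X, AX)
  XtAy <- crossprod(X, Ay)
  beta <- solve(XtAX, XtAy)
  resid <- y - X %*% beta
  q <- sum(resid * Au(resid))
  sigma2 <- q / N
  logdetM <- 2 * sum(log(diag(cM)))
  ll <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + logdetM + N)
  list(loglik = as.numeric(ll), beta = as.numeric(beta), sigma2 = sigma2,
       XtAX = XtAX)
}

#' Fit an MLPE mixed model of genetic distance on effective distance
#'
#' Maximum-likelihood fit of
#' \eqn{y_{ij} = \mu + \beta x_{ij} + \epsilon_{ij}} where observations
#' sharing exactly one individual have correlation \eqn{\rho \in [0, 0.5)}
#' (the maximum-likelihood population effects covariance). The predictor is
#' standardized (z-score of the lower triangle) so that slopes and AICc are
#' invariant to cost-unit conventions. ML, not REML, so AICc is comparable
#' across fixed-effect structures.
#'
#' @param genetic response `dist_matrix`.
#' @param effective predictor `dist_matrix` (effective or geographic
#'   distance) with the same labels.
#' @param name model label used in ranking tables.
#' @return An object of class `mlpe_fit` with elements `beta` (standardized
#'   slope), `intercept`, `rho`, `sigma2` (residual variance), `loglik`,
#'   `k` (4: two fixed effects + rho + sigma2), `n_pairs`, `beta_se`,
#'   `converged`.
#' @export
mlpe_fit <- function(genetic, effective, name = "model") {
  check_same_labels(genetic, effective)
  labels <- dist_labels(genetic)
  n <- length(labels)
  y <- lower_tri_vec(genetic)
  x <- lower_tri_vec(effective)
  if (any(!is.finite(x)))
    stop("effective distances contain non-finite values (disconnected pairs?)")
  if (stats::sd(x) == 0) stop("predictor has zero variance")
  x <- (x - mean(x)) / stats::sd(x)
  N <- length(y)
  pr <- pair_index(labels)
  Z <- matrix(0, N, n)
  Z[cbind(seq_len(N), pr$i)] <- 1
  Z[cbind(seq_len(N), pr$j)] <- 1
  X <- cbind(`(Intercept)` = 1, x = x)
  obj <- function(rho) {
    gamma <- rho / (1 - 2 * rho)
    -mlpe_profile(gamma, y, X, Z)$loglik
  }
  opt <- stats::optimize(obj, interval = c(0, 0.499), tol = 1e-7)
  # the optimum may sit at rho = 0; compare against the boundary explicitly
  ll0 <- -obj(0)
  if (ll0 >= -opt$objective) {
    rho <- 0; ll <- ll0
  } else {
    rho <- opt$minimum; ll <- -opt$objective
  }
  prof <- mlpe_profile(rho / (1 - 2 * rho), y, X, Z)
  vbeta <- prof$sigma2 * solve(prof$XtAX)
  structure(list(name = name, beta = prof$beta[2], intercept = prof$beta[1],
                 rho = rho, sigma2 = prof$sigma2, loglik = prof$loglik,
                 k = 4L, n_pairs = N, n_individuals = n,
                 beta_se = sqrt(vbeta[2, 2]), converged = TRUE),
            class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("<mlpe_fit> '%s': beta = %.4f (SE %.4f), rho = %.3f, logLik = %.2f, n_pairs = %d\n",
              x$name, x$beta, x$beta_se, x$rho, x$loglik, x$n_pairs))
  invisible(x)
}

#' @export
coef.mlpe_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, x = object$beta)
}

#' @export
logLik.mlpe_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_pairs,
            class = "logLik")
}

#' @export
summary.mlpe_fit <- function(object, ...) {
  ci <- object$beta + c(-1, 1) * stats::qnorm(0.975) * object$beta_se
  cat(sprintf(
    "MLPE fit '%s'\n  slope (standardized): %.4f  [%.4f, %.4f]\n  rho: %.4f  sigma2: %.5g\n  logLik %.3f on %d pairs (%d individuals), AICc %.3f\n",
    object$name, object$beta, ci[1], ci[2], object$rho, object$sigma2,
    object$loglik, object$n_pairs, object$n_individuals,
    aicc(object$loglik, object$k, object$n_pairs)))
  invisible(object)
}

#' Small-sample corrected Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed k + 1.
#' @return AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' @param aicc_values numeric vector.
#' @return weights w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2); sums to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank MLPE models by AICc
#'
#' Builds the model-selection table: AICc, delta AICc relative to the best
#' model, and Akaike weights, sorted ascending by AICc. The set should
#' include the isolation-by-distance null (geographic distance as the
#' predictor); all fits must share the same response data.
#'
#' @param fits named list of `mlpe_fit` objects.
#' @return a `model_table` data.frame with columns `model`, `loglik`, `k`,
#'   `AICc`, `dAICc`, `AICcWt`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  np <- vapply(fits, function(f) f$n_pairs, integer(1))
  if (length(unique(np)) != 1)
    stop("fits are not on identical response data (n_pairs differ)")
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) {
    warning(sprintf("excluding non-converged fit(s): %s",
                    paste(names(fits)[!conv], collapse = ", ")))
    fits <- fits[conv]
  }
  ac <- vapply(fits, function(f) aicc(f$loglik, f$k, f$n_pairs), numeric(1))
  tab <- data.frame(model = names(fits),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    k = vapply(fits, function(f) f$k, integer(1)),
                    AICc = ac)
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$AICcWt <- akaike_weights(tab$AICc)
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$AICc <- round(df$AICc, 2); df$dAICc <- round(df$dAICc, 2)
  df$AICcWt <- round(df$AICcWt, 3)
  print(df[, c("model", "AICc", "dAICc", "AICcWt")])
  invisible(x)
}
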