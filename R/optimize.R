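#' Optimize a feature's resistance value by constrained grid search
#'
#' For each candidate resistance on the sanctioned grid, builds the
#' univariate surface, computes least-cost effective distances between the
#' sampled cells, and scores the surface by a partial Mantel correlation of
#' genetic distance with effective distance, controlling for geographic
#' distance. Facilitator mode evaluates the single 1-vs-100 surface.
#'
#' @param feature a `feature_layer`.
#' @param mode `"barrier"` or `"facilitator"`; layers with role `"both"` are
#'   run once per mode by the caller.
#' @param genetic,geographic `dist_matrix` objects over the same individuals.
#' @param cells snapped (row, col) sampling cells, one row per individual.
#' @param value_grid candidate barrier values (default [BARRIER_VALUE_GRID]).
#' @param n_perm,seed permutation settings passed to [partial_mantel()].
#' @return An `optimization_trace`: data.frame of (feature, mode, value, r,
#'   p) plus attributes `selected_value` and `rule_applied`.
#' @export
optimize_univariate <- function(feature, mode = c("barrier", "facilitator"),
                                genetic, geographic, cells,
                                value_grid = BARRIER_VALUE_GRID,
                                n_perm = 999, seed = 1) {
  mode <- match.arg(mode)
  check_same_labels(genetic, geographic)
  labels <- dist_labels(genetic)
  vals <- if (mode == "barrier") sort(value_grid) else 1
  rows <- list()
  for (v in vals) {
    surf <- build_univariate_surface(feature, mode,
                                     value = if (mode == "barrier") v else NULL,
                                     value_grid = value_grid)
    cd <- cost_distance_matrix(surf, cells, labels = labels)
    if (!is.null(cd$disconnected_pairs)) {
      warning(sprintf("feature '%s' value %g: disconnected pair(s); value skipped",
                      feature$name, v))
      next
    }
    mt <- partial_mantel(genetic, cd$distances, geographic,
                         n_perm = n_perm, seed = seed)
    rows[[length(rows) + 1L]] <-
      data.frame(feature = feature$name, mode = mode, value = v,
                 r = mt$r, p = mt$p, n_perm = n_perm, seed = seed)
  }
  if (!length(rows))
    stop(sprintf("feature '%s': every candidate value left pairs disconnected",
                 feature$name))
  trace <- do.call(rbind, rows)
  class(trace) <- c("optimization_trace", "data.frame")
  sel <- select_resistance(trace)
  attr(trace, "selected_value") <- sel$value
  attr(trace, "rule_applied") <- sel$rule
  trace
}

#' Peak/plateau selection of the optimal resistance value
#'
#' Applies the selection rule to an optimization trace: if the partial
#' Mantel r profile has a strict interior maximum (a unimodal peak), that
#' value is chosen; otherwise the smallest value whose r is within
#' `rel_tol` (relative) of the maximum is chosen -- the onset of the
#' plateau. If no value has positive support, the smallest candidate is
#' returned with a warning.
#'
#' @param trace an `optimization_trace` (or data.frame with columns `value`,
#'   `r`, sorted ascending by `value`).
#' @param rel_tol relative tolerance defining the plateau (default 0.01).
#' @return list with `value`, `rule` (`"peak"`, `"plateau"` or
#'   `"no_support"`), and `r` at the selected value.
#' @export
select_resistance <- function(trace, rel_tol = 0.01) {
  stopifnot(nrow(trace) >= 1)
  o <- order(trace$value)
  v <- trace$value[o]; r <- trace$r[o]
  if (length(v) == 1)
    return(list(value = v, rule = "peak", r = r))
  if (max(r) <= 0) {
    warning("no support: all partial Mantel r non-positive")
    return(list(value = v[1], rule = "no_support", r = r[1]))
  }
  k <- length(r)
  # peak rule: the *global* maximum of support, when it is interior and
  # strictly exceeds both neighbours (a unimodal peak, not a noise bump)
  imax <- which.max(r)
  if (imax > 1 && imax < k && r[imax] > r[imax - 1] && r[imax] > r[imax + 1])
    return(list(value = v[imax], rule = "peak", r = r[imax]))
  thr <- (1 - rel_tol) * max(r)
  first <- which(r >= thr)[1]
  list(value = v[first], rule = "plateau", r = r[first])
}

#' Write an optimization trace as CSV
#' @param trace an `optimization_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$selected <- df$value == attr(trace, "selected_value")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
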