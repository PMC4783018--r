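#' Sanctioned barrier resistance values
#'
#' The discrete grid of candidate barrier resistances tested against a
#' background of 1 during univariate optimization.
#' @export
BARRIER_VALUE_GRID <- c(2, 5, 10, 25, 50, 100, 250, 500, 750, 1000)

#' Background resistance assigned to non-feature cells when a feature is
#' tested as a facilitator (feature cells get 1).
#' @export
FACILITATOR_BACKGROUND <- 100

new_resistance_surface <- function(grid, provenance) {
  structure(list(grid = grid, provenance = provenance),
            class = "resistance_surface")
}

#' Wrap a raster grid as a resistance surface
#'
#' For custom surfaces built outside the univariate/multivariate
#' constructors. Every non-nodata cell must be >= 1 (the background value).
#'
#' @param grid a `raster_grid` (or bare matrix) of resistance values.
#' @param cell_size,origin_x,origin_y used when `grid` is a bare matrix.
#' @return a `resistance_surface` with empty provenance.
#' @export
resistance_surface <- function(grid, cell_size = 30, origin_x = 0,
                               origin_y = 0) {
  if (!inherits(grid, "raster_grid"))
    grid <- raster_grid(grid, cell_size, origin_x, origin_y)
  v <- grid$values
  if (any(v[!is.na(v)] < 1))
    stop("resistance values must be >= 1")
  new_resistance_surface(grid, data.frame(feature = character(0),
                                          role = character(0),
                                          value = numeric(0)))
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat("<resistance_surface>\n")
  print(x$grid)
  if (nrow(x$provenance))
    cat(sprintf("  features: %s\n",
                paste(sprintf("%s=%g", x$provenance$feature,
                              x$provenance$value), collapse = ", ")))
  invisible(x)
}

#' Build a univariate resistance surface
#'
#' Binary friction surface for one feature. In barrier mode the feature's
#' cells receive the candidate resistance and the background is 1; in
#' facilitator mode the feature's cells receive 1 against a background of
#' [FACILITATOR_BACKGROUND].
#'
#' @param feature a `feature_layer`.
#' @param mode `"barrier"` or `"facilitator"`.
#' @param value barrier resistance; must come from `value_grid`. Ignored in
#'   facilitator mode (fixed at 1).
#' @param value_grid sanctioned candidate values (default [BARRIER_VALUE_GRID]).
#' @return a `resistance_surface`.
#' @export
build_univariate_surface <- function(feature, mode = c("barrier", "facilitator"),
                                     value = NULL,
                                     value_grid = BARRIER_VALUE_GRID) {
  mode <- match.arg(mode)
  m <- feature$mask$values
  if (mode == "barrier") {
    if (is.null(value) || !value %in% value_grid)
      stop(sprintf("barrier value %s is not in the sanctioned grid (%s)",
                   format(value), paste(value_grid, collapse = ", ")))
    v <- ifelse(m == 1, value, 1)
    prov <- data.frame(feature = feature$name, role = "barrier", value = value)
  } else {
    if (!is.null(value) && value != 1)
      stop("facilitator mode uses a fixed resistance of 1")
    v <- ifelse(m == 1, 1, FACILITATOR_BACKGROUND)
    prov <- data.frame(feature = feature$name, role = "facilitator", value = 1)
  }
  v[is.na(m)] <- NA
  g <- feature$mask
  new_resistance_surface(raster_grid(v, g$cell_size, g$origin_x, g$origin_y),
                         prov)
}

# Indices of the 8-neighbourhood of the cells set in `mask` (logical matrix),
# excluding the cells themselves.
eight_neighbour_ring <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(FALSE, nr, nc))
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- idx[, 1] + dr; c <- idx[, 2] + dc
    keep <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out[cbind(r[keep], c[keep])] <- TRUE
  }
  out & !mask
}

#' Build a buffered-road resistance surface
#'
#' Models roads as simultaneous barriers and facilitators: road carriageway
#' cells carry their class's optimized barrier resistance, and for selected
#' classes every non-road cell 8-adjacent to the road receives a one-cell
#' facilitating strip of resistance 1 (the mowed/shrubby right-of-way).
#' Where road classes overlap, the largest resistance wins; road-cell status
#' always wins over buffer status.
#'
#' @param road_layers named list of `feature_layer`s, one per road class.
#' @param barrier_values named numeric vector of optimized per-class barrier
#'   resistances (same names as `road_layers`).
#' @param buffered_classes character vector of layer names whose flanks get
#'   the cost-1 buffer (possibly empty).
#' @return a `resistance_surface`; its provenance records carriageway and
#'   buffer assignments per class.
#' @export
build_buffered_road_surface <- function(road_layers, barrier_values,
                                        buffered_classes = character(0)) {
  stopifnot(length(road_layers) > 0)
  nms <- names(road_layers)
  if (is.null(nms) || !all(nms %in% names(barrier_values)))
    stop("every road layer needs a named barrier value")
  if (!all(buffered_classes %in% nms))
    stop("buffered_classes must name supplied road layers")
  g <- road_layers[[1]]$mask
  road_val <- matrix(0, nrow(g$values), ncol(g$values))
  overlap <- FALSE
  for (nm in nms) {
    m <- road_layers[[nm]]$mask$values == 1
    m[is.na(m)] <- FALSE
    if (any(road_val[m] > 0)) overlap <- TRUE
    road_val[m] <- pmax(road_val[m], barrier_values[[nm]])
  }
  if (overlap)
    message("overlapping road classes: highest resistance retained")
  is_road <- road_val > 0
  buf <- matrix(FALSE, nrow(road_val), ncol(road_val))
  for (nm in buffered_classes) {
    m <- road_layers[[nm]]$mask$values == 1
    m[is.na(m)] <- FALSE
    buf <- buf | eight_neighbour_ring(m)
  }
  buf <- buf & !is_road
  v <- matrix(1, nrow(road_val), ncol(road_val))
  v[is_road] <- road_val[is_road]
  v[buf] <- 1
  v[is.na(g$values)] <- NA
  prov <- data.frame(feature = nms, role = "road_barrier",
                     value = as.numeric(barrier_values[nms]),
                     buffered = nms %in% buffered_classes)
  new_resistance_surface(raster_grid(v, g$cell_size, g$origin_x, g$origin_y),
                         prov)
}

#' Compose a multivariate resistance surface
#'
#' Combines optimized univariate features into one surface under a fixed
#' precedence: starting from background 1, each cell takes the maximum value
#' over the barrier features covering it; facilitator features then set the
#' cells they cover to 1, except on road carriageway cells; finally the
#' roadside buffer strips of `road_spec` set flanking cells to 1. A model
#' containing only facilitators (no barriers, no roads) is built against the
#' univariate facilitator background of [FACILITATOR_BACKGROUND] instead, so
#' facilitator-only hypotheses remain non-degenerate.
#'
#' @param features list of lists with elements `layer` (a `feature_layer`),
#'   `role` (`"barrier"` or `"facilitator"` -- a layer declared `"both"` must
#'   arrive with its resolved role), and `value` (optimized resistance;
#'   facilitators use 1).
#' @param road_spec optional list with elements `road_layers`,
#'   `barrier_values`, `buffered_classes` as in
#'   [build_buffered_road_surface()], or `NULL` for no roads.
#' @return a `resistance_surface` whose provenance lists each feature with
#'   its role and value.
#' @export
compose_multivariate_surface <- function(features, road_spec = NULL) {
  stopifnot(length(features) > 0 || !is.null(road_spec))
  g <- if (length(features)) features[[1]]$layer$mask else
    road_spec$road_layers[[1]]$mask
  nr <- nrow(g$values); nc <- ncol(g$values)
  v <- matrix(1, nr, nc)
  prov <- list()
  for (f in features) {
    if (is.null(f$role) || f$role == "both")
      stop(sprintf("feature '%s' has unresolved role 'both'; supply barrier or facilitator",
                   f$layer$name))
    prov[[length(prov) + 1L]] <-
      data.frame(feature = f$layer$name, role = f$role,
                 value = if (f$role == "barrier") f$value else 1)
  }
  barr <- Filter(function(f) f$role == "barrier", features)
  fac <- Filter(function(f) f$role == "facilitator", features)
  # a facilitator-only model (no barriers, no roads) is built against the
  # univariate facilitator background of 100; with barriers present the
  # background stays 1 and facilitators act by overriding barrier cells
  if (!length(barr) && is.null(road_spec) && length(fac))
    v[] <- FACILITATOR_BACKGROUND
  for (f in barr) {
    m <- f$layer$mask$values == 1
    m[is.na(m)] <- FALSE
    v[m] <- pmax(v[m], f$value)
  }
  is_road <- matrix(FALSE, nr, nc)
  road_val <- NULL
  if (!is.null(road_spec)) {
    rs <- build_buffered_road_surface(road_spec$road_layers,
                                      road_spec$barrier_values,
                                      road_spec$buffered_classes %||% character(0))
    road_val <- rs$grid$values
    for (nm in names(road_spec$road_layers)) {
      m <- road_spec$road_layers[[nm]]$mask$values == 1
      m[is.na(m)] <- FALSE
      is_road <- is_road | m
    }
    v[is_road] <- pmax(v[is_road], road_val[is_road])
    prov[[length(prov) + 1L]] <-
      data.frame(feature = names(road_spec$road_layers), role = "road_barrier",
                 value = as.numeric(road_spec$barrier_values[
                   names(road_spec$road_layers)]))
  }
  for (f in fac) {
    m <- f$layer$mask$values == 1
    m[is.na(m)] <- FALSE
    v[m & !is_road] <- 1
  }
  if (!is.null(road_spec) && length(road_spec$buffered_classes %||% character(0))) {
    buf <- matrix(FALSE, nr, nc)
    for (nm in road_spec$buffered_classes) {
      m <- road_spec$road_layers[[nm]]$mask$values == 1
      m[is.na(m)] <- FALSE
      buf <- buf | eight_neighbour_ring(m)
    }
    v[buf & !is_road] <- 1
  }
  v[is.na(g$values)] <- NA
  new_resistance_surface(raster_grid(v, g$cell_size, g$origin_x, g$origin_y),
                         do.call(rbind, prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A priori multivariate model presets
#'
#' Named sets of feature labels for the standard multivariate hypotheses:
#' all barriers, natural barriers, natural facilitators, all facilitators,
#' linear (anthropogenic) facilitators, landcover-only, development + roads,
#' and the global model with every feature. Road layers are handled through
#' `road_spec` and are implied by presets that include roads.
#'
#' @param preset preset name.
#' @param with_lidar include the LiDAR-detected short-vegetation facilitator
#'   layer where the preset admits it.
#' @return list with `barriers`, `facilitators` (character vectors of feature
#'   names) and `roads` (logical: road layers included as barriers).
#' @export
multivariate_preset <- function(preset = c("all_barriers", "natural_barriers",
                                           "natural_facilitators",
                                           "all_facilitators",
                                           "linear_facilitators", "landcover",
                                           "development_roads", "global"),
                                with_lidar = TRUE) {
  preset <- match.arg(preset)
  lin <- c("powerline", "railroad")
  nat_fac <- c("palustrine_emergent_wetland", "scrub_shrub_wetland",
               "scrub_shrub")
  if (with_lidar) nat_fac <- c(nat_fac, "lidar_veg")
  nat_barr <- c("forested_wetland", "estuarine_emergent_wetland", "water",
                "fields")
  switch(preset,
    all_barriers = list(
      barriers = c("forest", nat_barr, "development"),
      facilitators = character(0), roads = TRUE),
    natural_barriers = list(barriers = nat_barr,
                            facilitators = character(0), roads = FALSE),
    natural_facilitators = list(barriers = character(0),
                                facilitators = nat_fac, roads = FALSE),
    all_facilitators = list(barriers = character(0),
                            facilitators = c(nat_fac, lin), roads = FALSE),
    linear_facilitators = list(barriers = character(0),
                               facilitators = lin, roads = FALSE),
    landcover = list(
      barriers = c("forest", nat_barr, "development"),
      facilitators = setdiff(nat_fac, "lidar_veg"), roads = FALSE),
    development_roads = list(barriers = "development",
                             facilitators = character(0), roads = TRUE),
    global = list(
      barriers = c("forest", nat_barr, "development"),
      facilitators = c(nat_fac, lin), roads = TRUE))
}
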