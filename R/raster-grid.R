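#' Raster grid
#'
#' Lightweight in-memory raster: a numeric matrix with a cell size (metres)
#' and the projected coordinates of the lower-left corner. Row 1 is the top
#' row, matching the ESRI ASCII grid layout; `NA` cells are nodata and are
#' treated as impassable by all connectivity operations.
#'
#' @param values numeric matrix of cell values (row 1 = northernmost row).
#' @param cell_size side length of a cell in metres; must be positive.
#' @param origin_x,origin_y projected coordinates (m) of the lower-left
#'   (south-west) corner of the grid.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 30, origin_x = 0, origin_y = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite cell values (other than NA nodata) are not allowed")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g m, origin (%g, %g)\n",
              d[1], d[2], x$cell_size, x$origin_x, x$origin_y))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

n_cells <- function(grid) prod(dim(grid$values))

#' Cell-centre coordinates of grid cells
#'
#' @param grid a `raster_grid`.
#' @param cells 2-column matrix of (row, col) indices (1-based).
#' @return 2-column matrix of projected (x, y) cell-centre coordinates.
#' @export
cell_centers <- function(grid, cells) {
  cells <- rbind(cells)
  nr <- nrow(grid$values)
  x <- grid$origin_x + (cells[, 2] - 0.5) * grid$cell_size
  y <- grid$origin_y + (nr - cells[, 1] + 0.5) * grid$cell_size
  cbind(x = x, y = y)
}

#' Snap projected points to grid cells
#'
#' Points are assigned to the cell whose square contains them; points on the
#' shared edge of two cells go to the cell with the larger row/column index,
#' except on the outer boundary.
#'
#' @param grid a `raster_grid`.
#' @param xy 2-column matrix of projected coordinates (m).
#' @return 2-column integer matrix of (row, col) indices.
#' @export
snap_points <- function(grid, xy) {
  xy <- rbind(xy)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((xy[, 1] - grid$origin_x) / grid$cell_size) + 1L
  row <- nr - floor((xy[, 2] - grid$origin_y) / grid$cell_size)
  col <- pmin(pmax(col, 1L), nc)
  row <- pmin(pmax(row, 1L), nr)
  bad <- xy[, 1] < grid$origin_x | xy[, 1] > grid$origin_x + nc * grid$cell_size |
         xy[, 2] < grid$origin_y | xy[, 2] > grid$origin_y + nr * grid$cell_size
  if (any(bad))
    stop(sprintf("point(s) outside grid bounds: %s",
                 paste(which(bad), collapse = ", ")))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, NODATA_value) followed by row-major values.
#'
#' @param path file path.
#' @return a `raster_grid`; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: missing ncols/nrows/cellsize header")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d values, found %d",
                 hdr$ncols * hdr$nrows, length(vals)))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  oy <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  raster_grid(m, cell_size = hdr$cellsize, origin_x = ox, origin_y = oy)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param nodata numeric code written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Feature layer
#'
#' A named binary mask over a grid together with its hypothesised role in
#' gene flow: `"barrier"` (elevated resistance), `"facilitator"` (reduced
#' resistance) or `"both"` (tested in either mode; reserved for fields and
#' wetland types, whose effect is ambiguous a priori).
#'
#' @param name feature label, e.g. `"forest"`, `"road_class_1"`.
#' @param mask a `raster_grid` with values in {0, 1} (NA allowed for nodata).
#' @param role one of `"barrier"`, `"facilitator"`, `"both"`.
#' @return An object of class `feature_layer`.
#' @export
feature_layer <- function(name, mask, role = c("barrier", "facilitator", "both")) {
  role <- match.arg(role)
  stopifnot(inherits(mask, "raster_grid"))
  v <- mask$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop(sprintf("feature '%s': mask values must be 0 or 1", name))
  if (role == "both" &&
      !grepl("^(fields|.*wetland.*)$", name))
    stop(sprintf("role 'both' is reserved for fields and wetland layers, not '%s'",
                 name))
  structure(list(name = name, mask = mask, role = role),
            class = "feature_layer")
}

#' @export
print.feature_layer <- function(x, ...) {
  cat(sprintf("<feature_layer> '%s' (%s): %d cells set\n", x$name, x$role,
              sum(x$mask$values == 1, na.rm = TRUE)))
  invisible(x)
}

# Supercover trace of one segment in continuous cell coordinates.
# a, b are length-2 (col_coord, row_coord) in units of cells measured from the
# grid's top-left corner (col to the right, row downward). Returns every cell
# (row, col) whose closed unit square the segment touches, including cells met
# only at a corner -- this is what stops a 1-cell road leaking diagonally.
supercover_segment <- function(a, b, nr, nc) {
  eps <- 1e-9
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  len <- max(abs(dx), abs(dy))
  if (len < eps) {
    r <- min(max(floor(a[2]) + 1L, 1L), nr)
    c <- min(max(floor(a[1]) + 1L, 1L), nc)
    return(matrix(c(r, c), 1, 2))
  }
  # crossing parameters of all horizontal and vertical grid lines the segment
  # spans, plus the endpoints; midpoints of consecutive crossings identify the
  # traversed cells, and points lying exactly on a line mark both neighbours
  tx <- if (abs(dx) > eps)
    (seq(floor(min(a[1], b[1])), ceiling(max(a[1], b[1]))) - a[1]) / dx
  else numeric(0)
  ty <- if (abs(dy) > eps)
    (seq(floor(min(a[2], b[2])), ceiling(max(a[2], b[2]))) - a[2]) / dy
  else numeric(0)
  ts <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
  pts <- cbind(a[1] + ts * dx, a[2] + ts * dy)
  cells <- list()
  push <- function(r, c) {
    if (r >= 1 && r <= nr && c >= 1 && c <= nc)
      cells[[length(cells) + 1L]] <<- c(r, c)
  }
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    on_vx <- abs(x - round(x)) < eps
    on_hy <- abs(y - round(y)) < eps
    # all cells whose closed square contains this point
    cs <- if (on_vx) c(round(x), round(x) + 1) else floor(x) + 1
    rs <- if (on_hy) c(round(y), round(y) + 1) else floor(y) + 1
    for (r in rs) for (c in cs) push(r, c)
    if (i < nrow(pts)) {          # midpoint of the next span
      xm <- (pts[i, 1] + pts[i + 1, 1]) / 2
      ym <- (pts[i, 2] + pts[i + 1, 2]) / 2
      push(floor(ym) + 1, floor(xm) + 1)
    }
  }
  m <- unique(do.call(rbind, cells))
  m
}

#' Rasterize a polyline as a linear feature layer
#'
#' Traces the polyline with a supercover rule (every cell whose square the
#' line touches is marked, so 1-cell-wide features have no diagonal gaps) and
#' optionally widens it to two cells to represent features wider than one
#' cell, such as multi-lane highways on a 30 m grid.
#'
#' @param path_vertices 2-column matrix of projected (x, y) vertices.
#' @param grid_template a `raster_grid` supplying extent and cell size.
#' @param width_cells total width of the rasterized line in cells (1 or 2).
#' @param name,role passed to [feature_layer()].
#' @return a `feature_layer` whose mask marks the traced cells.
#' @export
rasterize_polyline <- function(path_vertices, grid_template, width_cells = 1,
                               name = "line", role = "barrier") {
  if (is.null(path_vertices) || NROW(path_vertices) == 0)
    stop("empty vertex list")
  path_vertices <- rbind(path_vertices)
  if (!width_cells %in% c(1L, 2L)) stop("width_cells must be 1 or 2")
  nr <- nrow(grid_template$values); nc <- ncol(grid_template$values)
  cs <- grid_template$cell_size
  # continuous cell coordinates: u rightward from west edge, v downward from
  # north edge
  u <- (path_vertices[, 1] - grid_template$origin_x) / cs
  v <- nr - (path_vertices[, 2] - grid_template$origin_y) / cs
  bad <- u < -1e-9 | u > nc + 1e-9 | v < -1e-9 | v > nr + 1e-9
  if (any(bad))
    stop(sprintf("vertex %s outside grid bounds",
                 paste(which(bad), collapse = ", ")))
  mask <- matrix(0, nr, nc)
  nseg <- max(NROW(path_vertices) - 1L, 1L)
  for (s in seq_len(nseg)) {
    i2 <- if (NROW(path_vertices) == 1L) s else s + 1L
    cells <- supercover_segment(c(u[s], v[s]), c(u[i2], v[i2]), nr, nc)
    mask[cells] <- 1
    if (width_cells == 2L) {
      # widen on the side given by the segment's rounded unit normal; for an
      # axis-aligned segment this adds exactly one parallel row/column
      du <- u[i2] - u[s]; dv <- v[i2] - v[s]
      nrm <- sqrt(du^2 + dv^2)
      if (nrm == 0) { dr <- 1L; dc <- 0L } else {
        dr <- round(du / nrm); dc <- round(-dv / nrm)
        if (dr == 0 && dc == 0) dr <- 1L
      }
      shifted <- cells
      shifted[, 1] <- shifted[, 1] + dr
      shifted[, 2] <- shifted[, 2] + dc
      keep <- shifted[, 1] >= 1 & shifted[, 1] <= nr &
              shifted[, 2] >= 1 & shifted[, 2] <= nc
      mask[shifted[keep, , drop = FALSE]] <- 1
    }
  }
  mask[is.na(grid_template$values)] <- NA
  feature_layer(name,
                raster_grid(mask, cs, grid_template$origin_x,
                            grid_template$origin_y),
                role)
}
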