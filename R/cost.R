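# Shared 8-connectivity edge list for a resistance raster.
# Returns data.frame(from, to, rdist) of unique undirected edges between
# non-nodata cells; `rdist` is mean resistance of the two end cells times 1
# (rook) or sqrt(2) (diagonal). Node ids are the cells' column-major linear
# indices, so they are stable across calls.
surface_edges <- function(surface) {
  v <- surface$grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr * nc < 2) stop("connectivity needs at least 2 cells")
  if (all(is.na(v))) stop("surface is entirely nodata")
  if (any(v[!is.na(v)] < 1))
    stop("resistance values must be >= 1")
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  shift <- function(dr, dc, diag) {
    rf <- seq_len(nr - abs(dr)); rt <- rf + dr
    cf <- seq_len(nc - abs(dc)) + max(-dc, 0); ct <- cf + dc
    from <- as.vector(idx[rf, cf, drop = FALSE])
    to <- as.vector(idx[rt, ct, drop = FALSE])
    w <- (v[from] + v[to]) / 2 * if (diag) sqrt(2) else 1
    ok <- !is.na(w)
    data.frame(from = from[ok], to = to[ok], rdist = w[ok])
  }
  # east, south, south-east, south-west
  rbind(shift(0, 1, FALSE), shift(1, 0, FALSE),
        shift(1, 1, TRUE), shift(1, -1, TRUE))
}

cells_to_nodes <- function(surface, cells) {
  cells <- rbind(cells)
  nr <- nrow(surface$grid$values)
  nodes <- (cells[, 2] - 1L) * nr + cells[, 1]
  onnd <- is.na(surface$grid$values[cells])
  if (any(onnd))
    stop(sprintf("point(s) on nodata cells: rows %s",
                 paste(which(onnd), collapse = ", ")))
  nodes
}

nodes_to_cells <- function(surface, nodes) {
  nr <- nrow(surface$grid$values)
  cbind(row = (nodes - 1L) %% nr + 1L, col = (nodes - 1L) %/% nr + 1L)
}

surface_graph <- function(surface) {
  e <- surface_edges(surface)
  g <- igraph::make_empty_graph(n = n_cells(surface$grid), directed = FALSE)
  g <- igraph::add_edges(g, rbind(e$from, e$to))
  igraph::E(g)$weight <- e$rdist
  g
}

#' Cost distances between sampled cells on a resistance surface
#'
#' Exact shortest-path (Dijkstra) cumulative costs under 8-connectivity with
#' edge weight = mean resistance of the two cells, times sqrt(2) for diagonal
#' moves. Costs are in resistance x cell-length units (cell size is a global
#' factor and is not multiplied in); geographic distance is carried
#' separately in metres.
#'
#' @param surface a `resistance_surface` (all values >= 1).
#' @param cells 2-column (row, col) matrix of snapped sampling cells.
#' @param labels optional individual labels for the output matrix.
#' @return list with `distances` (a `dist_matrix` of kind `effective`;
#'   `Inf` for disconnected pairs, which are also flagged in
#'   `disconnected_pairs`) and `graph` (the underlying igraph, reusable by
#'   [least_cost_path()]).
#' @export
cost_distance_matrix <- function(surface, cells, labels = NULL) {
  nodes <- cells_to_nodes(surface, cells)
  g <- surface_graph(surface)
  un <- unique(nodes)                 # cells may be sampled more than once
  du <- igraph::distances(g, v = un, to = un, algorithm = "dijkstra")
  d <- du[match(nodes, un), match(nodes, un), drop = FALSE]
  d <- (d + t(d)) / 2                 # enforce exact symmetry
  if (is.null(labels)) labels <- paste0("p", seq_along(nodes))
  dm <- new_dist_matrix(d, labels, "effective")
  disc <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
  list(distances = dm,
       disconnected_pairs = if (nrow(disc))
         data.frame(i = labels[disc[, 1]], j = labels[disc[, 2]]) else NULL,
       graph = g, nodes = nodes, surface_id = attr(surface, "id"))
}

#' Least-cost path between two cells
#'
#' @param surface a `resistance_surface`.
#' @param a,b length-2 (row, col) cell indices.
#' @param graph optional pre-built graph from [cost_distance_matrix()].
#' @return list with `path` (matrix of (row, col) cells from `a` to `b`),
#'   `cost` (cumulative cost), and `disconnected` (logical).
#' @export
least_cost_path <- function(surface, a, b, graph = NULL) {
  nodes <- cells_to_nodes(surface, rbind(a, b))
  if (is.null(graph)) graph <- surface_graph(surface)
  sp <- suppressWarnings(
    igraph::shortest_paths(graph, from = nodes[1], to = nodes[2],
                           output = "both"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0)
    return(list(path = NULL, cost = Inf, disconnected = TRUE))
  cost <- if (length(sp$epath[[1]]))
    sum(igraph::E(graph)$weight[as.integer(sp$epath[[1]])]) else 0
  list(path = nodes_to_cells(surface, as.integer(vp)), cost = cost,
       disconnected = FALSE)
}

#' Rasterize least-cost paths to a path-count grid
#'
#' Counts, per cell, how many of the supplied paths traverse it.
#'
#' @param surface the `resistance_surface` the paths were computed on.
#' @param paths list of path matrices as returned by [least_cost_path()].
#' @return a `raster_grid` of counts.
#' @export
path_count_raster <- function(surface, paths) {
  v <- matrix(0, nrow(surface$grid$values), ncol(surface$grid$values))
  for (p in paths) if (!is.null(p)) {
    u <- unique(p)
    v[u] <- v[u] + 1
  }
  v[is.na(surface$grid$values)] <- NA
  g <- surface$grid
  raster_grid(v, g$cell_size, g$origin_x, g$origin_y)
}

#' Write paths as a GeoJSON FeatureCollection of LineStrings
#'
#' Path vertices are cell centres in the grid's projected coordinates.
#'
#' @param surface the `resistance_surface` carrying the georeference.
#' @param paths named list of path matrices.
#' @param path output file.
#' @export
write_paths_geojson <- function(surface, paths, path) {
  feats <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (is.null(p)) return(NULL)
    xy <- cell_centers(surface$grid, p)
    list(type = "Feature",
         properties = list(pair = nm),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(xy)),
                                              function(i) c(xy[i, 1], xy[i, 2]))))
  })
  fc <- list(type = "FeatureCollection",
             features = Filter(Negate(is.null), feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
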