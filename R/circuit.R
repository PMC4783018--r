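#' Build a circuit network from a resistance surface
#'
#' Every non-nodata cell becomes a node; 8-neighbouring cells are joined by a
#' resistor whose conductance is the mean of the two cell conductances
#' (1/resistance), divided by sqrt(2) for diagonal neighbours. This matches
#' the cost engine's average-resistance edges on uniform surfaces.
#'
#' @param surface a `resistance_surface`.
#' @return An object of class `circuit_network`: node index per cell, sparse
#'   edge list with conductances, and the graph Laplacian.
#' @export
build_network <- function(surface) {
  v <- surface$grid$values
  if (all(is.na(v))) stop("surface is entirely nodata")
  keep <- which(!is.na(v))                 # column-major cell ids
  node_of <- integer(length(v)); node_of[keep] <- seq_along(keep)
  e <- surface_edges(surface)
  g_from <- 1 / v[e$from]; g_to <- 1 / v[e$to]
  cond <- (g_from + g_to) / 2
  diagonal <- abs((e$from - 1) %/% nrow(v) - (e$to - 1) %/% nrow(v)) == 1 &
              abs((e$from - 1) %% nrow(v) - (e$to - 1) %% nrow(v)) == 1
  cond[diagonal] <- cond[diagonal] / sqrt(2)
  i <- node_of[e$from]; j <- node_of[e$to]
  nn <- length(keep)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(cond, cond),
                            dims = c(nn, nn))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  structure(list(n_nodes = nn, cells = keep, node_of = node_of,
                 edges = data.frame(i = i, j = j, conductance = cond),
                 laplacian = L, grid = surface$grid),
            class = "circuit_network")
}

#' @export
print.circuit_network <- function(x, ...) {
  cat(sprintf("<circuit_network> %d nodes, %d resistors\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

net_node <- function(net, cell) {
  id <- (cell[2] - 1L) * nrow(net$grid$values) + cell[1]
  nd <- net$node_of[id]
  if (nd == 0L) stop("focal element on a nodata cell")
  nd
}

# Solve L_grounded v = b with node `ground` removed (v[ground] = 0).
# Direct sparse Cholesky: deterministic and well below 1e-8 relative error
# at the scales this package targets.
solve_grounded <- function(L, ground, b) {
  keep <- setdiff(seq_len(nrow(L)), ground)
  v <- numeric(nrow(L))
  sol <- Matrix::solve(L[keep, keep, drop = FALSE], b[keep])
  v[keep] <- as.numeric(sol)
  v
}

#' Two-point effective resistance
#'
#' Injects unit current at `a`, extracts it at `b`, solves the Laplacian
#' system and returns the voltage difference.
#'
#' @param net a `circuit_network`.
#' @param a,b length-2 (row, col) cells.
#' @return effective resistance (ohm-equivalent, resistance units of the
#'   surface); `Inf` if the cells are in different components.
#' @export
effective_resistance <- function(net, a, b) {
  na_ <- net_node(net, a); nb <- net_node(net, b)
  if (na_ == nb) return(0)
  comp <- igraph_components(net)
  if (comp[na_] != comp[nb]) return(Inf)
  bvec <- numeric(net$n_nodes)
  bvec[na_] <- 1
  v <- solve_grounded(net$laplacian, nb, bvec)
  v[na_] - v[nb]
}

igraph_components <- function(net) {
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, net$n_nodes - igraph::vcount(g)))
  igraph::components(g)$membership
}

# Contract focal patches to super-nodes. `focal` is a list whose elements are
# either a single (row, col) cell (length-2 vector / 1-row matrix) or a
# multi-row matrix of member cells (a focal patch treated as one node).
# Returns the contracted Laplacian, the super-node index of each focal
# element, and a map from contracted nodes back to original nodes.
contract_focals <- function(net, focal) {
  group <- seq_len(net$n_nodes)
  focal_nodes <- vector("list", length(focal))
  for (k in seq_along(focal)) {
    cells <- rbind(focal[[k]])
    nds <- vapply(seq_len(nrow(cells)),
                  function(i) net_node(net, cells[i, ]), integer(1))
    group[nds] <- nds[1]                 # merge patch members
    focal_nodes[[k]] <- nds[1]
  }
  ug <- sort(unique(group))
  remap <- match(group, ug)
  nn <- length(ug)
  e <- net$edges
  i <- remap[e$i]; j <- remap[e$j]
  keep <- i != j                          # drop intra-patch resistors
  A <- Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                            x = rep(e$conductance[keep], 2), dims = c(nn, nn))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  list(laplacian = L, remap = remap,
       focal = vapply(focal_nodes, function(nd) remap[nd], integer(1)))
}

#' All-to-one current map
#'
#' For each focal element in turn: ground it, inject unit current at every
#' other focal element, solve the network, and accumulate per-cell current
#' magnitude (half the sum of absolute branch currents incident to the
#' cell). Focal patches (multi-cell elements) are contracted to single
#' super-nodes before solving; member cells all receive the super-node's
#' current.
#'
#' @param net a `circuit_network`.
#' @param focal list of focal elements: length-2 (row, col) cells or
#'   multi-row matrices of patch member cells. At least 2.
#' @return list with `current` (a `raster_grid` of accumulated current,
#'   `NA` on nodata), `mode = "all_to_one"`, and `n_solves`.
#' @export
solve_all_to_one <- function(net, focal) {
  if (length(focal) < 2) stop("need at least 2 focal elements")
  ctr <- contract_focals(net, focal)
  L <- ctr$laplacian
  nn <- nrow(L)
  e_i <- ctr$remap[net$edges$i]; e_j <- ctr$remap[net$edges$j]
  econd <- net$edges$conductance
  node_cur <- numeric(nn)
  for (k in seq_along(ctr$focal)) {
    bvec <- numeric(nn)
    bvec[ctr$focal[-k]] <- 1
    v <- solve_grounded(L, ctr$focal[k], bvec)
    branch <- abs(v[e_i] - v[e_j]) * econd
    keep <- e_i != e_j
    cur <- numeric(nn)
    tab_i <- tapply(branch[keep], e_i[keep], sum)
    tab_j <- tapply(branch[keep], e_j[keep], sum)
    cur[as.integer(names(tab_i))] <- cur[as.integer(names(tab_i))] + tab_i
    cur[as.integer(names(tab_j))] <- cur[as.integer(names(tab_j))] + tab_j
    node_cur <- node_cur + cur / 2
  }
  vals <- matrix(NA_real_, nrow(net$grid$values), ncol(net$grid$values))
  vals[net$cells] <- node_cur[ctr$remap]
  g <- net$grid
  list(current = raster_grid(vals, g$cell_size, g$origin_x, g$origin_y),
       mode = "all_to_one", n_solves = length(ctr$focal))
}
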