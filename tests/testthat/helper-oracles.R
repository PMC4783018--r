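# Independent oracles used across the suite. These deliberately avoid the
# package's own graph/edge construction: everything is recomputed from first
# principles with naive loops.

surf <- function(m, cell_size = 30) resistance_surface(m, cell_size)

rand_dist <- function(n, seed, kind = "geographic") {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(2 * n), n)))
  landres:::new_dist_matrix(m, sprintf("i%02d", seq_len(n)), kind)
}

# Exhaustive edge-relaxation shortest paths (Bellman-Ford style): 8-neighbour
# moves, edge cost = mean of the two cell resistances, sqrt(2) on diagonals.
brute_force_costs <- function(m, cells) {
  nr <- nrow(m); nc <- ncol(m)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(m[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(m[r2, c2])) next
      w <- (m[r, c] + m[r2, c2]) / 2 * if (dr != 0 && dc != 0) sqrt(2) else 1
      edges[[length(edges) + 1L]] <- c(id(r, c), id(r2, c2), w)
    }
  }
  E <- do.call(rbind, edges)
  k <- nrow(cells)
  out <- matrix(Inf, k, k)
  for (s in seq_len(k)) {
    d <- rep(Inf, nr * nc)
    d[id(cells[s, 1], cells[s, 2])] <- 0
    repeat {
      nd <- pmin(d, Inf)
      relax <- d[E[, 1]] + E[, 3]
      better <- relax < nd[E[, 2]]
      if (!any(better)) break
      for (ii in which(better))
        nd[E[ii, 2]] <- min(nd[E[ii, 2]], d[E[ii, 1]] + E[ii, 3])
      if (identical(nd, d)) break
      d <- nd
    }
    out[s, ] <- d[id(cells[, 1], cells[, 2])]
  }
  out
}

# Dense-pseudoinverse circuit oracle: node voltages from the Moore-Penrose
# inverse of the full Laplacian, naive per-edge currents, half-sum per node.
dense_circuit_oracle <- function(m, focal_cells) {
  nr <- nrow(m); nc <- ncol(m)
  keep <- which(!is.na(m))
  node_of <- integer(nr * nc); node_of[keep] <- seq_along(keep)
  nn <- length(keep)
  L <- matrix(0, nn, nn)
  elist <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(m[r, c])) next
    for (dd in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(m[r2, c2])) next
      g <- (1 / m[r, c] + 1 / m[r2, c2]) / 2
      if (dd[1] != 0 && dd[2] != 0) g <- g / sqrt(2)
      i <- node_of[(c - 1) * nr + r]; j <- node_of[(c2 - 1) * nr + r2]
      L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
      L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
      elist[[length(elist) + 1L]] <- c(i, j, g)
    }
  }
  E <- do.call(rbind, elist)
  Lp <- MASS::ginv(L)
  focal <- vapply(focal_cells, function(cc)
    node_of[(cc[2] - 1) * nr + cc[1]], integer(1))
  cur <- numeric(nn)
  for (k in seq_along(focal)) {
    b <- numeric(nn)
    b[focal[-k]] <- 1
    b[focal[k]] <- -(length(focal) - 1)
    v <- Lp %*% b
    half <- numeric(nn)
    for (ii in seq_len(nrow(E))) {
      br <- abs(v[E[ii, 1]] - v[E[ii, 2]]) * E[ii, 3]
      half[E[ii, 1]] <- half[E[ii, 1]] + br
      half[E[ii, 2]] <- half[E[ii, 2]] + br
    }
    cur <- cur + half / 2
  }
  out <- matrix(NA_real_, nr, nc)
  out[keep] <- cur
  out
}

# Does the closed segment a-b intersect the closed unit cell (row, col)?
# Liang-Barsky clipping in continuous cell coordinates (x right, y down).
segment_hits_cell <- function(a, b, row, col) {
  xmin <- col - 1; xmax <- col; ymin <- row - 1; ymax <- row
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  t0 <- 0; t1 <- 1
  for (side in list(c(-dx, a[1] - xmin), c(dx, xmax - a[1]),
                    c(-dy, a[2] - ymin), c(dy, ymax - a[2]))) {
    p <- side[1]; q <- side[2]
    if (abs(p) < 1e-12) {
      if (q < -1e-12) return(FALSE)
    } else {
      t <- q / p
      if (p < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1 + 1e-12) return(FALSE)
    }
  }
  TRUE
}

brute_force_supercover <- function(vertices_xy, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  u <- (vertices_xy[, 1] - grid$origin_x) / cs
  v <- nr - (vertices_xy[, 2] - grid$origin_y) / cs
  hit <- matrix(FALSE, nr, nc)
  for (s in seq_len(nrow(vertices_xy) - 1)) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!hit[r, c] &&
          segment_hits_cell(c(u[s], v[s]), c(u[s + 1], v[s + 1]), r, c))
        hit[r, c] <- TRUE
    }
  }
  hit
}

# Independent Rousset's a: direct enumeration of allelic-identity counts.
rousset_a_oracle <- function(calls) {
  n <- dim(calls)[1]; L <- dim(calls)[2]
  qw <- numeric(L)
  for (l in seq_len(L)) {
    ident <- c()
    for (i in seq_len(n)) {
      g <- calls[i, l, ]
      if (!anyNA(g)) ident <- c(ident, as.integer(g[1] == g[2]))
    }
    qw[l] <- mean(ident)
  }
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- den <- 0
    for (l in seq_len(L)) {
      gi <- calls[i, l, ]; gj <- calls[j, l, ]
      if (anyNA(gi) || anyNA(gj)) next
      cmp <- c(gi[1] == gj[1], gi[1] == gj[2], gi[2] == gj[1], gi[2] == gj[2])
      num <- num + qw[l] - mean(cmp)
      den <- den + 1 - qw[l]
    }
    a[i, j] <- a[j, i] <- num / den
  }
  a
}

random_genotypes <- function(n, L, seed, missing_rate = 0.05,
                             n_alleles = 6) {
  set.seed(seed)
  calls <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    if (stats::runif(1) < missing_rate) next
    calls[i, l, ] <- sample.int(n_alleles, 2, replace = TRUE) + 10L
  }
  # guarantee every pair shares a co-typed locus
  calls[, 1, 1][is.na(calls[, 1, 1])] <- 11L
  calls[, 1, 2][is.na(calls[, 1, 2])] <- 12L
  genotype_table(sprintf("i%02d", seq_len(n)), sprintf("L%02d", seq_len(L)),
                 calls, data.frame(x = stats::runif(n, 0, 1000),
                                   y = stats::runif(n, 0, 1000)))
}
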