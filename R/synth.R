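#' Default study-area landcover compositions
#'
#' Proportions of each landcover class for the two emulated study areas: a
#' rural, forest-dominated area and a suburban, development-heavy area.
#' Remaining area is forest background. Roads and LiDAR speckle overlay the
#' landcover and are not counted in the composition.
#'
#' @name area_compositions
#' @export
kittery_composition <- function() {
  c(development = 0.112, fields = 0.111, scrub_shrub = 0.046,
    forested_wetland = 0.074, scrub_shrub_wetland = 0.015,
    palustrine_emergent_wetland = 0.010, estuarine_emergent_wetland = 0.010,
    water = 0.033)
}

#' @rdname area_compositions
#' @export
cape_composition <- function() {
  c(development = 0.286, fields = 0.089, scrub_shrub = 0.039,
    forested_wetland = 0.093, scrub_shrub_wetland = 0.011,
    palustrine_emergent_wetland = 0.021, estuarine_emergent_wetland = 0.092,
    water = 0.031)
}

feature_role_of <- function(name) {
  if (grepl("^road_class_", name)) return("barrier")
  switch(name,
         forest = , development = , water = "barrier",
         scrub_shrub = , powerline = , railroad = , lidar_veg = "facilitator",
         fields = , forested_wetland = , scrub_shrub_wetland = ,
         palustrine_emergent_wetland = , estuarine_emergent_wetland = "both",
         stop(sprintf("unknown feature '%s'", name)))
}

# Grow `target` cells from random seeds by frontier expansion (4-neighbour),
# over cells still available in `free`. Returns a logical matrix.
grow_blobs <- function(free, target, mean_blob_cells = 120) {
  nr <- nrow(free); nc <- ncol(free)
  out <- matrix(FALSE, nr, nc)
  placed <- 0L
  avail <- which(free)
  n_seeds <- max(1L, round(target / mean_blob_cells))
  seeds <- sample(avail, min(n_seeds, length(avail)))
  frontier <- seeds
  out[seeds] <- TRUE; free[seeds] <- FALSE
  placed <- length(seeds)
  while (placed < target && length(frontier)) {
    cur <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
    nb <- c(if (r > 1) cur - 1L, if (r < nr) cur + 1L,
            if (c > 1) cur - nr, if (c < nc) cur + nr)
    nb <- nb[free[nb]]
    if (!length(nb)) {
      frontier <- setdiff(frontier, cur)
      if (!length(frontier) && placed < target) {
        # reseed if blobs ran out of room
        avail <- which(free)
        if (!length(avail)) break
        s <- sample(avail, 1)
        out[s] <- TRUE; free[s] <- FALSE; placed <- placed + 1L
        frontier <- s
      }
      next
    }
    take <- nb[sample.int(length(nb), 1)]
    out[take] <- TRUE; free[take] <- FALSE
    placed <- placed + 1L
    frontier <- c(frontier, take)
  }
  out
}

random_crossing_line <- function(grid, horizontal, jitter = 0.15) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  W <- nc * cs; H <- nr * cs
  n_pts <- 4
  if (horizontal) {
    y0 <- stats::runif(1, 0.15, 0.85) * H
    xs <- seq(0, W, length.out = n_pts)
    ys <- y0 + stats::rnorm(n_pts, 0, jitter * H)
    ys <- pmin(pmax(ys, cs), H - cs)
    xs[1] <- 1e-6; xs[n_pts] <- W - 1e-6
  } else {
    x0 <- stats::runif(1, 0.15, 0.85) * W
    ys <- seq(0, H, length.out = n_pts)
    xs <- x0 + stats::rnorm(n_pts, 0, jitter * W)
    xs <- pmin(pmax(xs, cs), W - cs)
    ys[1] <- 1e-6; ys[n_pts] <- H - 1e-6
  }
  cbind(grid$origin_x + xs, grid$origin_y + ys)
}

#' Generate a synthetic landscape with feature layers
#'
#' Emulates a fragmented New England coastal landscape at 30 m resolution:
#' blob-shaped landcover patches grown to target class proportions over a
#' forest background, polyline roads of up to 6 traffic classes (class 1 is
#' two cells / 60 m wide, the rest one cell), a powerline and a railroad
#' line, and an optional sparse speckle of LiDAR-detected 1-3 m vegetation
#' covering about 1 percent of the landscape.
#'
#' @param composition named vector of class proportions (sum <= 1; remainder
#'   is forest). Defaults to [kittery_composition()].
#' @param nrow,ncol grid dimensions in cells.
#' @param cell_size cell side in metres (default 30).
#' @param road_classes integer vector of road classes to draw (subset of 1:6).
#' @param lidar_cover proportion of cells speckled as LiDAR-detected
#'   vegetation (0 to disable; default 0.01).
#' @param seed RNG seed; the same seed reproduces the map bit-for-bit.
#' @return list with `landcover` (a `raster_grid` of integer class codes),
#'   `layers` (named list of `feature_layer`s with their default roles),
#'   `class_codes`, `composition`, `seed`.
#' @export
generate_landscape <- function(composition = kittery_composition(),
                               nrow = 100, ncol = 100, cell_size = 30,
                               road_classes = 1:6, lidar_cover = 0.01,
                               seed = 1) {
  if (sum(composition) > 1)
    stop("class proportions must sum to at most 1")
  set.seed(seed)
  template <- raster_grid(matrix(1, nrow, ncol), cell_size)
  N <- nrow * ncol
  codes <- c(forest = 1L, development = 2L, fields = 3L, scrub_shrub = 4L,
             water = 5L, forested_wetland = 6L, scrub_shrub_wetland = 7L,
             palustrine_emergent_wetland = 8L,
             estuarine_emergent_wetland = 9L)
  lc <- matrix(codes[["forest"]], nrow, ncol)
  free <- matrix(TRUE, nrow, ncol)
  for (cls in names(composition)) {
    if (!cls %in% names(codes)) stop(sprintf("unknown landcover class '%s'", cls))
    target <- round(composition[[cls]] * N)
    if (target == 0) next
    blob <- grow_blobs(free, target)
    lc[blob] <- codes[[cls]]
    free <- free & !blob
  }
  layers <- list()
  for (cls in names(codes)) {
    mask <- raster_grid((lc == codes[[cls]]) * 1, cell_size)
    layers[[cls]] <- feature_layer(cls, mask, feature_role_of(cls))
  }
  for (k in road_classes) {
    nm <- sprintf("road_class_%d", k)
    verts <- random_crossing_line(template, horizontal = k %% 2 == 0)
    layers[[nm]] <- rasterize_polyline(verts, template,
                                       width_cells = if (k == 1) 2L else 1L,
                                       name = nm, role = "barrier")
  }
  for (nm in c("powerline", "railroad")) {
    verts <- random_crossing_line(template, horizontal = stats::runif(1) < 0.5)
    layers[[nm]] <- rasterize_polyline(verts, template, width_cells = 1L,
                                       name = nm, role = "facilitator")
  }
  if (lidar_cover > 0) {
    speck <- matrix(0, nrow, ncol)
    speck[sample.int(N, round(lidar_cover * N))] <- 1
    layers[["lidar_veg"]] <- feature_layer(
      "lidar_veg", raster_grid(speck, cell_size), "facilitator")
  }
  list(landcover = raster_grid(lc, cell_size), layers = layers,
       class_codes = codes, composition = composition, seed = seed)
}

#' Generate a gapped-band barrier layer for value-recovery studies
#'
#' Vertical barrier bands spanning the grid, most carrying a single gap at a
#' random height while every third band is complete. Gapped bands force
#' detours whose length depends on position rather than on straight-line
#' separation, which decorrelates cost distance from geographic distance and
#' keeps the resistance value identifiable by partial Mantel correlation
#' across the whole candidate grid; complete bands add pure crossing costs.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param n_bands number of vertical bands.
#' @param cell_size cell side in metres.
#' @param seed RNG seed.
#' @return a `feature_layer` (role `"barrier"`).
#' @export
generate_barrier_bands <- function(nrow = 100, ncol = 100, n_bands = 6,
                                   cell_size = 30, seed = 1) {
  set.seed(seed)
  mask <- matrix(0, nrow, ncol)
  cols <- sort(sample(seq(10, ncol - 10), n_bands))
  for (i in seq_along(cols)) {
    mask[, cols[i]] <- 1
    if (i %% 3 != 0) {
      gap <- sample(5:(nrow - 5), 1)
      mask[gap + (-1:1), cols[i]] <- 0
    }
  }
  feature_layer("water", raster_grid(mask, cell_size), "barrier")
}

#' Generate pairwise genetic distances from cost distances
#'
#' Direct isolation-by-resistance generator for calibrating the optimizer
#' and model-selection machinery: genetic distance is an affine function of
#' the standardized cost distance plus MLPE-correlated noise, in which pairs
#' sharing an individual are correlated `rho` through per-individual random
#' effects.
#'
#' @param cost a `dist_matrix` of effective distances (finite).
#' @param beta_true slope on the standardized cost distance (>= 0).
#' @param noise_sd total noise standard deviation per pair.
#' @param rho shared-individual correlation, in \[0, 0.5\].
#' @param mu intercept (default 0).
#' @param seed RNG seed.
#' @return a `dist_matrix` of kind `genetic_a` (synthetic).
#' @export
generate_pairwise_genetic <- function(cost, beta_true, noise_sd = 1,
                                      rho = 0.25, mu = 0, seed = 1) {
  if (beta_true < 0) stop("beta_true must be >= 0")
  if (rho < 0 || rho > 0.5) stop("rho must lie in [0, 0.5]")
  labels <- dist_labels(cost)
  n <- length(labels)
  x <- lower_tri_vec(cost)
  if (any(!is.finite(x))) stop("cost matrix has non-finite entries")
  z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  set.seed(seed)
  sd_ind <- sqrt(rho) * noise_sd
  sd_e <- sqrt(max(1 - 2 * rho, 0)) * noise_sd
  a <- stats::rnorm(n, 0, sd_ind)
  pr <- pair_index(labels)
  e <- stats::rnorm(length(z), 0, sd_e)
  y <- mu + beta_true * z + a[pr$i] + a[pr$j] + e
  new_dist_matrix(tri_to_matrix(y, n), labels, "genetic_a")
}

#' Forward-time genotype simulation on a deme network
#'
#' Finite-island Wright-Fisher simulation with stepwise-mutating
#' microsatellites: demes sit on occupied patch cells, per-generation
#' migration between demes decays exponentially with the cost distance
#' between them (m_ab proportional to exp(-lambda cost_ab), scaled so each
#' deme retains at least `1 - emigration` of its gene pool), and alleles
#' mutate by +/-1 repeat with probability `mutation_rate`.
#'
#' @param patch_cells list of (row, col) cells, one per deme (sampling
#'   coordinates come from these cells).
#' @param cost symmetric matrix of cost distances between demes.
#' @param grid a `raster_grid` used to convert patch cells to coordinates.
#' @param lambda migration-distance decay rate (>= 0); large lambda isolates
#'   demes, 0 gives equal exchange among all demes.
#' @param deme_size diploid individuals per deme.
#' @param mutation_rate per-allele per-generation stepwise mutation rate.
#' @param n_generations generations to run.
#' @param n_loci number of microsatellite loci (default 11).
#' @param sample_sizes individuals sampled per deme (recycled).
#' @param emigration total emigration rate per deme per generation
#'   (default 0.2, so self-retention >= 0.8).
#' @param seed RNG seed.
#' @return a `genotype_table`; individual labels encode the deme.
#' @export
simulate_genotypes_forward <- function(patch_cells, cost, grid, lambda = 0.01,
                                       deme_size = 50, mutation_rate = 5e-4,
                                       n_generations = 200, n_loci = 11,
                                       sample_sizes = 10, emigration = 0.2,
                                       seed = 1) {
  nd <- length(patch_cells)
  stopifnot(nd >= 2, all(dim(cost) == nd))
  if (emigration <= 0 || emigration > 0.2 + 1e-12)
    stop("emigration must be in (0, 0.2] so self-retention stays >= 0.8")
  set.seed(seed)
  W <- exp(-lambda * cost)
  diag(W) <- 0
  M <- matrix(0, nd, nd)
  for (a in seq_len(nd)) {
    s <- sum(W[a, ])
    if (!is.finite(s)) stop(sprintf("unnormalizable migration row for deme %d", a))
    if (s > 0) M[a, ] <- emigration * W[a, ] / s
    M[a, a] <- 1 - sum(M[a, -a])
  }
  n2 <- 2L * deme_size
  # pools[[d]] : n2 x n_loci allele (repeat count) matrix
  pools <- lapply(seq_len(nd), function(d)
    matrix(sample(18:22, n2 * n_loci, replace = TRUE), n2, n_loci))
  for (gen in seq_len(n_generations)) {
    new_pools <- vector("list", nd)
    for (d in seq_len(nd)) {
      src <- sample.int(nd, n2, replace = TRUE, prob = M[d, ])
      al <- matrix(0L, n2, n_loci)
      for (s in unique(src)) {
        rows <- which(src == s)
        pick <- sample.int(n2, length(rows), replace = TRUE)
        al[rows, ] <- pools[[s]][pick, , drop = FALSE]
      }
      mut <- matrix(stats::runif(n2 * n_loci) < mutation_rate, n2, n_loci)
      if (any(mut))
        al[mut] <- al[mut] + sample(c(-1L, 1L), sum(mut), replace = TRUE)
      new_pools[[d]] <- pmax(al, 2L)
    }
    pools <- new_pools
  }
  sample_sizes <- rep_len(sample_sizes, nd)
  ids <- character(0); calls <- list(); xs <- ys <- numeric(0)
  areas <- character(0)
  for (d in seq_len(nd)) {
    take <- sample.int(deme_size, sample_sizes[d])
    ctr <- cell_centers(grid, rbind(patch_cells[[d]]))
    for (ii in take) {
      ids <- c(ids, sprintf("d%02d_i%02d", d, ii))
      g1 <- pools[[d]][2 * ii - 1, ]; g2 <- pools[[d]][2 * ii, ]
      calls[[length(calls) + 1L]] <- cbind(g1, g2)
      # jitter within the patch cell so sampling points are distinct
      xs <- c(xs, ctr[1] + stats::runif(1, -0.4, 0.4) * grid$cell_size)
      ys <- c(ys, ctr[2] + stats::runif(1, -0.4, 0.4) * grid$cell_size)
      areas <- c(areas, sprintf("deme%d", d))
    }
  }
  arr <- array(NA_integer_, c(length(ids), n_loci, 2))
  for (i in seq_along(ids)) arr[i, , ] <- calls[[i]]
  genotype_table(ids, sprintf("loc%02d", seq_len(n_loci)), arr,
                 data.frame(x = xs, y = ys), area_tag = areas)
}
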