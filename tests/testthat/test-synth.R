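test_that("landscape generation hits target class proportions", {
  land <- generate_landscape(kittery_composition(), nrow = 200, ncol = 200,
                             seed = 42)
  lc <- land$landcover$values
  for (cls in names(kittery_composition())) {
    got <- mean(lc == land$class_codes[[cls]])
    expect_lt(abs(got - kittery_composition()[[cls]]), 0.02)
  }
  # forest takes the remainder
  expect_lt(abs(mean(lc == 1) - (1 - sum(kittery_composition()))), 0.02)
  # lidar speckle covers about 1%
  expect_lt(abs(mean(land$layers$lidar_veg$mask$values) - 0.01), 0.005)
})

test_that("landscape generation is reproducible and validates input", {
  l1 <- generate_landscape(nrow = 40, ncol = 40, seed = 7)
  l2 <- generate_landscape(nrow = 40, ncol = 40, seed = 7)
  expect_identical(l1$landcover$values, l2$landcover$values)
  expect_identical(l1$layers$road_class_1$mask$values,
                   l2$layers$road_class_1$mask$values)
  l3 <- generate_landscape(nrow = 40, ncol = 40, seed = 8)
  expect_false(identical(l1$landcover$values, l3$landcover$values))
  expect_error(generate_landscape(c(development = 0.7, forest = 0.5)),
               "at most 1")
  # only forest: uniform map
  l4 <- generate_landscape(stats::setNames(numeric(0), character(0)),
                           nrow = 20, ncol = 20, road_classes = integer(0),
                           lidar_cover = 0, seed = 1)
  expect_true(all(l4$landcover$values == 1))
})

test_that("class-1 roads are two cells wide, minor roads one", {
  land <- generate_landscape(nrow = 80, ncol = 80, road_classes = c(1, 5),
                             seed = 11)
  # a width-2 crossing line covers at least ~2 cells per row/column spanned
  expect_gte(sum(land$layers$road_class_1$mask$values), 2 * 0.9 * 80)
  # a width-1 line stays close to the supercover of a single traverse
  expect_lte(sum(land$layers$road_class_5$mask$values), 2.5 * 80)
})

test_that("the pairwise generator honours its noise model", {
  cost <- rand_dist(20, 31, "effective")
  # noiseless: Mantel r = 1
  g0 <- generate_pairwise_genetic(cost, beta_true = 0.7, noise_sd = 0,
                                  rho = 0, seed = 1)
  expect_equal(mantel(g0, cost, n_perm = 99, seed = 1)$r, 1, tolerance = 1e-9)
  expect_equal(unclass(g0), t(unclass(g0)))
  expect_equal(diag(unclass(g0)), setNames(rep(0, 20), rownames(g0)))
  # null: r centred on zero
  rs <- vapply(1:40, function(s)
    mantel(generate_pairwise_genetic(cost, 0, noise_sd = 1, rho = 0.2,
                                     seed = s),
           cost, n_perm = 99, seed = s)$r, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(generate_pairwise_genetic(cost, -1, seed = 1), "beta_true")
  expect_error(generate_pairwise_genetic(cost, 1, rho = 0.7, seed = 1), "rho")
})

test_that("residuals of pairs sharing an individual correlate at rho", {
  cost <- rand_dist(25, 77, "effective")
  pr <- landres:::pair_index(rownames(cost))
  share <- which(outer(seq_len(nrow(pr)), seq_len(nrow(pr)),
                       Vectorize(function(a, b) a < b &&
                         length(intersect(c(pr$i[a], pr$j[a]),
                                          c(pr$i[b], pr$j[b]))) == 1)),
                 arr.ind = TRUE)
  set.seed(1)
  share <- share[sample(nrow(share), 2000), ]
  rho_hat <- mean(vapply(1:100, function(s) {
    g <- generate_pairwise_genetic(cost, 0, noise_sd = 1, rho = 0.3, seed = s)
    y <- landres:::lower_tri_vec(g)
    cor(y[share[, 1]], y[share[, 2]])
  }, numeric(1)))
  expect_lt(abs(rho_hat - 0.3), 0.04)
})

test_that("forward simulation produces isolation and panmixia limits", {
  grid <- raster_grid(matrix(1, 20, 20), 30)
  cells <- list(c(3, 3), c(3, 17), c(17, 3), c(17, 17))
  cost <- matrix(100, 4, 4); diag(cost) <- 0
  # lambda large: isolated demes diverge
  gt_iso <- simulate_genotypes_forward(cells, cost, grid, lambda = 10,
                                       deme_size = 20, n_generations = 120,
                                       mutation_rate = 5e-3,
                                       sample_sizes = 5, seed = 3)
  d <- dps_matrix(gt_iso)
  area <- gt_iso$area_tag
  within <- unclass(d)[outer(area, area, "==") & upper.tri(d)]
  between <- unclass(d)[outer(area, area, "!=") & upper.tri(d)]
  expect_gt(mean(between), mean(within))
  # per-deme means: every between-deme pair exceeds the within-deme mean
  for (d1 in unique(area)) for (d2 in setdiff(unique(area), d1)) {
    b <- mean(unclass(d)[area == d1, area == d2])
    expect_gt(b, mean(within))
  }
  # lambda = 0: panmixia over demes
  gt_pan <- simulate_genotypes_forward(cells, cost, grid, lambda = 0,
                                       deme_size = 20, n_generations = 120,
                                       mutation_rate = 5e-3,
                                       sample_sizes = 5, seed = 4)
  a <- rousset_a_matrix(gt_pan)
  area2 <- gt_pan$area_tag
  wi <- mean(unclass(a)[outer(area2, area2, "==") & upper.tri(a)])
  bw <- mean(unclass(a)[outer(area2, area2, "!=") & upper.tri(a)])
  expect_lt(abs(bw - wi), 0.05)
  expect_error(simulate_genotypes_forward(cells, cost, grid,
                                          emigration = 0.5, seed = 1),
               "0.2")
})

test_that("duplicate samples of one simulated individual have Dps zero", {
  grid <- raster_grid(matrix(1, 10, 10), 30)
  cells <- list(c(2, 2), c(8, 8))
  cost <- matrix(c(0, 10, 10, 0), 2, 2)
  gt <- simulate_genotypes_forward(cells, cost, grid, deme_size = 10,
                                   n_generations = 30, sample_sizes = 3,
                                   seed = 9)
  calls <- gt$calls
  calls[2, , ] <- calls[1, , ]           # clone individual 1 into slot 2
  gt2 <- genotype_table(gt$individuals, gt$loci, calls, gt$coords)
  expect_equal(dps_matrix(gt2)[1, 2], 0)
})
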