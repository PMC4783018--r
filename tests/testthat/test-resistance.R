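mk_mask <- function(m) raster_grid(m, 30)

test_that("univariate surfaces follow barrier and facilitator conventions", {
  m <- matrix(0, 4, 4); m[2, 2:3] <- 1
  forest <- feature_layer("forest", mk_mask(m), "barrier")
  s <- build_univariate_surface(forest, "barrier", 10)
  expect_equal(s$grid$values[2, 2], 10)
  expect_equal(s$grid$values[1, 1], 1)
  expect_equal(sum(s$grid$values == 10), 2)
  scrub <- feature_layer("scrub_shrub", mk_mask(m), "facilitator")
  sf <- build_univariate_surface(scrub, "facilitator")
  expect_equal(sf$grid$values[2, 2], 1)
  expect_equal(sf$grid$values[1, 1], 100)
  # empty mask in barrier mode: uniform background
  empty <- feature_layer("water", mk_mask(matrix(0, 4, 4)), "barrier")
  expect_true(all(build_univariate_surface(empty, "barrier", 50)$grid$values == 1))
  # off-grid value rejected
  expect_error(build_univariate_surface(forest, "barrier", 17), "sanctioned")
})

test_that("buffered roads get a one-cell cost-1 strip on each side", {
  m <- matrix(0, 5, 7); m[3, ] <- 1
  rd <- list(road_class_2 = feature_layer("road_class_2", mk_mask(m), "barrier"))
  s <- build_buffered_road_surface(rd, c(road_class_2 = 250),
                                   buffered_classes = "road_class_2")
  expect_true(all(s$grid$values[3, ] == 250))
  expect_true(all(s$grid$values[2, ] == 1))
  expect_true(all(s$grid$values[4, ] == 1))
  expect_true(all(s$grid$values[c(1, 5), ] == 1))
  # with no buffering it reduces to the per-class barrier surface
  s0 <- build_buffered_road_surface(rd, c(road_class_2 = 250))
  u <- build_univariate_surface(rd[[1]], "barrier", 250)
  expect_equal(s0$grid$values, u$grid$values)
})

test_that("two parallel roads one cell apart match the hand construction", {
  m1 <- matrix(0, 7, 7); m1[3, ] <- 1
  m2 <- matrix(0, 7, 7); m2[5, ] <- 1
  rd <- list(road_class_1 = feature_layer("road_class_1", mk_mask(m1), "barrier"),
             road_class_4 = feature_layer("road_class_4", mk_mask(m2), "barrier"))
  s <- build_buffered_road_surface(rd, c(road_class_1 = 500, road_class_4 = 50),
                                   buffered_classes = names(rd))
  expect_hand <- matrix(1, 7, 7)
  expect_hand[3, ] <- 500
  expect_hand[5, ] <- 50
  # rows 2, 4, 6 are buffers (value 1), row 4 shared by both roads
  expect_equal(s$grid$values, expect_hand)
  expect_true(all(s$grid$values[4, ] == 1))
})

test_that("overlapping road classes keep the larger resistance", {
  m <- matrix(0, 5, 5); m[3, ] <- 1
  rd <- list(road_class_1 = feature_layer("road_class_1", mk_mask(m), "barrier"),
             road_class_5 = feature_layer("road_class_5", mk_mask(m), "barrier"))
  expect_message(
    s <- build_buffered_road_surface(rd, c(road_class_1 = 750, road_class_5 = 25)),
    "highest")
  expect_true(all(s$grid$values[3, ] == 750))
})

test_that("multivariate composition applies the documented precedence", {
  barr_m <- matrix(0, 5, 5); barr_m[2, 1:3] <- 1
  fac_m <- matrix(0, 5, 5); fac_m[4, 2:4] <- 1
  feats <- list(
    list(layer = feature_layer("forest", mk_mask(barr_m), "barrier"),
         role = "barrier", value = 10),
    list(layer = feature_layer("scrub_shrub", mk_mask(fac_m), "facilitator"),
         role = "facilitator", value = 1))
  s <- compose_multivariate_surface(feats)
  expect_equal(s$grid$values[2, 1], 10)
  expect_equal(s$grid$values[4, 2], 1)
  expect_equal(s$grid$values[1, 1], 1)
  # facilitator overlapping a barrier cell wins off-road
  fac2 <- matrix(0, 5, 5); fac2[2, 2] <- 1
  feats2 <- c(feats[1], list(
    list(layer = feature_layer("scrub_shrub", mk_mask(fac2), "facilitator"),
         role = "facilitator", value = 1)))
  s2 <- compose_multivariate_surface(feats2)
  expect_equal(s2$grid$values[2, 2], 1)
  expect_equal(s2$grid$values[2, 1], 10)
  # unresolved "both" role errors
  bad <- list(list(layer = feature_layer("fields", mk_mask(fac2), "both"),
                   role = "both", value = 5))
  expect_error(compose_multivariate_surface(bad), "unresolved")
})

test_that("facilitators never override road carriageway cells", {
  road_m <- matrix(0, 5, 5); road_m[3, ] <- 1
  fac_m <- matrix(0, 5, 5); fac_m[3, 3] <- 1; fac_m[1, 1] <- 1
  feats <- list(
    list(layer = feature_layer("scrub_shrub", mk_mask(fac_m), "facilitator"),
         role = "facilitator", value = 1))
  rs <- list(road_layers = list(road_class_2 =
               feature_layer("road_class_2", mk_mask(road_m), "barrier")),
             barrier_values = c(road_class_2 = 250),
             buffered_classes = "road_class_2")
  s <- compose_multivariate_surface(feats, rs)
  expect_equal(s$grid$values[3, 3], 250)   # road wins over facilitator
  expect_equal(s$grid$values[1, 1], 1)
  expect_true(all(s$grid$values[2, ] == 1))  # buffer strip
})

test_that("composition is idempotent and matches per-cell brute force", {
  per_cell_oracle <- function(feats, road_mask, road_value, buffered) {
    nr <- nrow(feats[[1]]$layer$mask$values)
    nc <- ncol(feats[[1]]$layer$mask$values)
    out <- matrix(1, nr, nc)
    buf_ring <- if (buffered) {
      ring <- matrix(FALSE, nr, nc)
      idx <- which(road_mask == 1, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) for (dr in -1:1) for (dc in -1:1) {
        r <- idx[k, 1] + dr; c <- idx[k, 2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) ring[r, c] <- TRUE
      }
      ring & road_mask != 1
    } else matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      v <- 1
      for (f in feats) if (f$role == "barrier" &&
                           f$layer$mask$values[r, c] == 1)
        v <- max(v, f$value)
      if (road_mask[r, c] == 1) v <- max(v, road_value)
      for (f in feats) if (f$role == "facilitator" &&
                           f$layer$mask$values[r, c] == 1 &&
                           road_mask[r, c] != 1)
        v <- 1
      if (buf_ring[r, c] && road_mask[r, c] != 1) v <- 1
      out[r, c] <- v
    }
    out
  }
  for (s in 1:5) {
    set.seed(400 + s)
    mk <- function() matrix(rbinom(400, 1, 0.2), 20, 20)
    road_mask <- matrix(0, 20, 20); road_mask[sample(5:15, 1), ] <- 1
    feats <- list(
      list(layer = feature_layer("forest", mk_mask(mk()), "barrier"),
           role = "barrier", value = 100),
      list(layer = feature_layer("development", mk_mask(mk()), "barrier"),
           role = "barrier", value = 500),
      list(layer = feature_layer("scrub_shrub", mk_mask(mk()), "facilitator"),
           role = "facilitator", value = 1))
    rs <- list(road_layers = list(road_class_3 =
                 feature_layer("road_class_3", mk_mask(road_mask), "barrier")),
               barrier_values = c(road_class_3 = 250),
               buffered_classes = "road_class_3")
    s1 <- compose_multivariate_surface(feats, rs)
    s2 <- compose_multivariate_surface(feats, rs)
    expect_identical(s1$grid$values, s2$grid$values)
    oracle <- per_cell_oracle(feats, road_mask, 250, buffered = TRUE)
    expect_equal(s1$grid$values, oracle)
    # value census agrees with the oracle
    expect_equal(as.vector(table(s1$grid$values)),
                 as.vector(table(oracle)))
  }
})

test_that("buffered and barrier-only road surfaces differ exactly on buffers", {
  m <- matrix(0, 9, 9); m[5, ] <- 1
  rd <- list(road_class_2 = feature_layer("road_class_2", mk_mask(m), "barrier"))
  s_buf <- build_buffered_road_surface(rd, c(road_class_2 = 100),
                                       buffered_classes = "road_class_2")
  s_bar <- build_buffered_road_surface(rd, c(road_class_2 = 100))
  diff_cells <- which(s_buf$grid$values != s_bar$grid$values)
  expect_true(length(diff_cells) == 0)  # background already 1 on both
  # difference appears when background is raised by another barrier
  forest <- matrix(1, 9, 9)
  feats <- list(list(layer = feature_layer("forest", mk_mask(forest), "barrier"),
                     role = "barrier", value = 10))
  rs_buf <- compose_multivariate_surface(feats, list(
    road_layers = rd, barrier_values = c(road_class_2 = 100),
    buffered_classes = "road_class_2"))
  rs_bar <- compose_multivariate_surface(feats, list(
    road_layers = rd, barrier_values = c(road_class_2 = 100),
    buffered_classes = character(0)))
  d <- which(rs_buf$grid$values != rs_bar$grid$values, arr.ind = TRUE)
  expect_true(all(d[, 1] %in% c(4, 6)))          # exactly the flanking rows
  expect_equal(nrow(d), 18)
  expect_true(all(rs_buf$grid$values[d] == 1))
})
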