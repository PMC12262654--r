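test_that("observed G follows the subset nearest-neighbor definition", {
  pp <- point_pattern(cbind(c(0, 1, 5), c(0, 0, 0)))
  s <- subset_spec(2, c(TRUE, TRUE, FALSE))
  grid <- radius_grid(c(0.5, 2))
  expect_equal(observed_g(pp, s, grid)$g, c(0, 1))
  # a single marked point has no same-mark neighbor at any radius
  s1 <- subset_spec(1, c(TRUE, FALSE, FALSE))
  expect_equal(observed_g(pp, s1, grid)$g, c(0, 0))
  expect_error(observed_g(pp, subset_spec(2), grid), "mask")
})

test_that("full-subset observed G matches the neighbor-count identity", {
  pp <- unit_square_pattern(25, seed = 41)
  grid <- radius_grid(seq(0, 0.4, length.out = 8))
  s <- subset_spec(25, rep(TRUE, 25))
  g <- observed_g(pp, s, grid)$g
  counts <- neighbor_counts(pp, grid)
  expect_equal(g, colMeans(counts >= 1))
})

test_that("observed G is invariant to point reordering", {
  pp <- unit_square_pattern(20, seed = 42)
  grid <- radius_grid(seq(0, 0.5, length.out = 6))
  mask <- rep(c(TRUE, FALSE), 10)
  perm <- rev(seq_len(20))
  pp2 <- point_pattern(pp$coords[perm, ], window = pp$window)
  expect_equal(observed_g(pp, subset_spec(10, mask), grid)$g,
               observed_g(pp2, subset_spec(10, mask[perm]), grid)$g)
})

test_that("permutation null is seeded, summarized, and convergent", {
  pp <- unit_square_pattern(30, seed = 43)
  grid <- radius_grid(seq(0, 0.25, length.out = 20))
  p1 <- permuted_csr(pp, 5, grid, n_perm = 200, seed = 7)
  p2 <- permuted_csr(pp, 5, grid, n_perm = 200, seed = 7)
  expect_identical(p1, p2) # same seed, bit-identical
  expect_equal(p1$kind, "permutation_mean")
  expect_length(p1$sd, 20)
  expect_true(all(p1$lower <= p1$upper))
  expect_true(all(p1$lower >= 0 & p1$upper <= 1))
  expect_equal(p1$n_replicates, 200L)
  expect_error(permuted_csr(pp, 5, grid, n_perm = 200), "seed")
  expect_error(permuted_csr(pp, 5, grid, n_perm = 0, seed = 1), "n_perm")

  # the caller's RNG stream is not disturbed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(permuted_csr(pp, 5, grid, n_perm = 10, seed = 7))
  expect_identical(runif(1), before)

  # n = N: a single possible subset, so zero spread
  pN <- permuted_csr(pp, 30, grid, n_perm = 50, seed = 1)
  expect_equal(pN$sd, rep(0, 20))
  expect_equal(pN$g, observed_g(pp, subset_spec(30, rep(TRUE, 30)), grid)$g)

  # Monte-Carlo convergence to the exact mean (deterministic given seed)
  exact <- exact_mean_g(neighbor_counts(pp, grid), 5)
  pm <- permuted_csr(pp, 5, grid, n_perm = 5000, seed = 11)
  se <- pm$sd / sqrt(5000)
  expect_true(all(abs(pm$g - exact) <= 4 * se + 1e-12))
})

test_that("exhaustive enumeration is the definitional ground truth", {
  pp <- unit_square_pattern(10, seed = 44)
  grid <- radius_grid(seq(0, 0.7, length.out = 10))
  bf <- brute_force_csr(pp, 3, grid)
  expect_equal(bf$n_subsets, 120L)
  expect_equal(bf$mean$kind, "enumeration_mean")
  # against a direct loop over all subsets
  subsets <- utils::combn(10, 3)
  gmat <- apply(subsets, 2, function(s) bf_subset_g(pp$coords, s, grid))
  expect_equal(bf$mean$g, rowMeans(gmat), tolerance = 1e-12)
  expect_equal(bf$variance, apply(gmat, 1, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-12)

  # single-subset edge case
  pp5 <- unit_square_pattern(5, seed = 45)
  bf5 <- brute_force_csr(pp5, 5, grid)
  expect_equal(bf5$n_subsets, 1L)
  expect_equal(bf5$variance, rep(0, 10))
  expect_equal(bf5$mean$g, observed_g(pp5, subset_spec(5, rep(TRUE, 5)), grid)$g)

  expect_error(brute_force_csr(pp, 3, grid, cap = 100), "120.*cap|cap.*120")
})

test_that("theoretical Poisson curve is the textbook cdf", {
  grid <- radius_grid(c(0, 0.1, 0.5, 1, 3))
  g <- theoretical_poisson_g(grid, intensity = 2)
  expect_equal(g$g[1], 0)
  expect_true(all(diff(g$g) > 0))
  r_half <- sqrt(log(2) / (2 * pi)) # intensity*pi*r^2 = ln 2
  expect_equal(theoretical_poisson_g(radius_grid(r_half), intensity = 2)$g, 0.5)
  expect_gt(theoretical_poisson_g(radius_grid(100), intensity = 2)$g, 1 - 1e-10)
  # intensity derived from a window
  pp <- point_pattern(cbind(0.5, 0.5), window = c(0, 2, 0, 2))
  gd <- theoretical_poisson_g(grid, pattern = pp, n = 8)
  expect_equal(gd$g, 1 - exp(-2 * pi * as.numeric(grid)^2))
  expect_error(theoretical_poisson_g(grid), "intensity")
})
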