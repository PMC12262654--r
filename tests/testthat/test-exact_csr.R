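test_that("log_binom is exact for small arguments and flags impossibles", {
  expect_equal(log_binom(5, 2), log(10))
  expect_equal(log_binom(4, 0), 0)
  expect_identical(log_binom(3, 5), -Inf)
  expect_identical(log_binom(3, -1), -Inf)
  expect_error(log_binom(-1, 0), "non-negative")
  # cross-check against base R's lchoose over a grid
  a <- rep(0:40, each = 45)
  k <- rep(-2:42, times = 41)
  expect_equal(log_binom(a, k), lchoose(a, k), tolerance = 1e-12)
})

test_that("prob_no_neighbor matches exhaustive companion enumeration", {
  # N = 5, n = 3, p has 2 neighbors: companions are all C(4, 2) pairs of
  # the other 4 points; count those avoiding both neighbors
  companions <- utils::combn(4, 2)
  avoid <- mean(apply(companions, 2, function(s) !any(s %in% c(1, 2))))
  expect_equal(avoid, 1 / 6)
  expect_equal(prob_no_neighbor(2, N = 5, n = 3), avoid)
  # general enumeration: any n_p, N = 7, n = 4
  companions <- utils::combn(6, 3)
  for (np in 0:6) {
    oracle <- mean(apply(companions, 2, function(s) !any(s %in% seq_len(np))))
    expect_equal(prob_no_neighbor(np, N = 7, n = 4), oracle, tolerance = 1e-14)
  }
  expect_equal(prob_no_neighbor(0, N = 10, n = 4), 1)
  expect_equal(prob_no_neighbor(5, N = 10, n = 1), 1)
  expect_equal(prob_no_neighbor(8, N = 10, n = 3), 0) # too few non-neighbors
  expect_error(prob_no_neighbor(10, N = 10, n = 3), "n_p")
})

test_that("exact mean hits its analytic limits", {
  pp <- point_pattern(cbind(runif(8, 0, 0.01), runif(8, 0, 0.01)))
  counts <- neighbor_counts(pp, radius_grid(1))
  expect_equal(counts[, 1], rep(7L, 8)) # everyone neighbors everyone
  expect_equal(exact_mean_g(counts, 2), 1)
  expect_equal(exact_mean_g(counts, 1), 0)
  expect_error(exact_mean_g(counts, 9), "exceeds")
})

test_that("exact mean equals the full-enumeration average", {
  pp <- unit_square_pattern(10, seed = 31)
  grid <- radius_grid(seq(0, 0.7, length.out = 15))
  counts <- neighbor_counts(pp, grid)
  subsets <- utils::combn(10, 3) # all 120 subsets
  gmat <- apply(subsets, 2, function(s) bf_subset_g(pp$coords, s, grid))
  expect_equal(exact_mean_g(counts, 3), rowMeans(gmat), tolerance = 1e-10)
  # monotone, bounded
  m <- exact_mean_g(counts, 3)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("pair success probabilities match subset enumeration", {
  # Case 1 by hand: N = 4, n = 2, a direct pair succeeds iff both selected
  pp4 <- point_pattern(cbind(c(0, 0.1, 5, 9), c(0, 0, 0, 0)))
  ps4 <- pair_structure(pp4, 0.5)
  c4 <- neighbor_counts(pp4, radius_grid(0.5))[, 1]
  expect_equal(joint_success_prob(1, 2, ps4, c4, N = 4, n = 2), 1 / 6)
  # Case 2 with two isolated points: no success is possible
  expect_equal(joint_success_prob(3, 4, ps4, c4, N = 4, n = 2), 0)
  expect_error(joint_success_prob(1, 2, ps4, c4, N = 4, n = 1), "n >= 2")

  # all pairs of a 12-point pattern against the 495-subset enumeration
  pp <- unit_square_pattern(12, seed = 32)
  r <- 0.3
  ps <- pair_structure(pp, r)
  cr <- neighbor_counts(pp, radius_grid(r))[, 1]
  D <- as.matrix(dist(pp$coords))
  subsets <- utils::combn(12, 4)
  succeeds <- function(p, s) any(D[p, setdiff(s, p)] < r)
  for (p in 1:11) for (q in (p + 1):12) {
    freq <- mean(apply(subsets, 2, function(s) {
      all(c(p, q) %in% s) && succeeds(p, s) && succeeds(q, s)
    }))
    expect_equal(joint_success_prob(p, q, ps, cr, N = 12, n = 4), freq,
                 tolerance = 1e-12)
  }
})

test_that("exact variance equals the enumerated population variance", {
  pp <- unit_square_pattern(12, seed = 33)
  grid <- radius_grid(seq(0, 0.8, length.out = 12))
  bf <- brute_force_csr(pp, 4, grid)
  res <- exact_var_g(pp, grid, 4)
  expect_equal(res$mean, bf$mean$g, tolerance = 1e-10)
  expect_equal(res$variance, bf$variance, tolerance = 1e-10)
  expect_true(all(res$variance >= 0 & res$variance <= 0.25))
  expect_equal(res$sd, sqrt(res$variance))
})

test_that("moment and covariance variance decompositions agree", {
  for (seed in c(34, 35)) {
    pp <- unit_square_pattern(15, seed = seed)
    grid <- radius_grid(seq(0, 0.9, length.out = 10))
    v1 <- exact_var_g(pp, grid, 5)$variance
    v2 <- exact_var_g(pp, grid, 5, method = "covariance")$variance
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("variance degenerates exactly where it must", {
  pp <- unit_square_pattern(9, seed = 36)
  grid <- radius_grid(c(0, 0.2, 5)) # last radius beyond the diameter
  # n = N: only one subset exists
  res <- exact_var_g(pp, grid, 9)
  expect_equal(res$variance, rep(0, 3))
  s_all <- subset_spec(9, rep(TRUE, 9))
  expect_equal(res$mean, observed_g(pp, s_all, grid)$g)
  # r beyond diameter: G_S is 1 for every subset
  res2 <- exact_var_g(pp, grid, 3)
  expect_equal(res2$mean[3], 1)
  expect_equal(res2$variance[3], 0)
  # n = 1: degenerate with a warning, not an error
  expect_warning(res1 <- exact_var_g(pp, grid, 1), "n <= 1")
  expect_equal(res1$mean, rep(0, 3))
  expect_equal(res1$variance, rep(0, 3))
  # cost warning above the configured threshold
  big <- unit_square_pattern(60, seed = 37)
  expect_warning(exact_var_g(big, radius_grid(0.1), 5, warn_threshold = 50),
                 "O\\(N\\^2\\)")
})

test_that("closed-radius convention is honored consistently end to end", {
  # boundary-heavy pattern: integer grid distances equal to several radii
  pp <- point_pattern(cbind(c(0, 1, 2, 3), c(0, 0, 0, 0)))
  grid <- radius_grid(c(1, 2))
  for (closed in c(FALSE, TRUE)) {
    bf <- brute_force_csr(pp, 2, grid, closed = closed)
    res <- exact_var_g(pp, grid, 2, closed = closed)
    expect_equal(res$mean, bf$mean$g, tolerance = 1e-12)
    expect_equal(res$variance, bf$variance, tolerance = 1e-12)
  }
  # and the two conventions genuinely differ on this pattern
  expect_false(isTRUE(all.equal(exact_var_g(pp, grid, 2)$mean,
                                exact_var_g(pp, grid, 2, closed = TRUE)$mean)))
})
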