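#' Log binomial coefficient with impossible-selection sentinel
#'
#' `log_binom(a, k)` returns log C(a, k) evaluated through log-gamma, the
#' numerically stable route for the binomial-coefficient ratios that the
#' exact CSR formulas are built from. Selections that cannot occur
#' (`k < 0` or `k > a`) return `-Inf`, so that `exp()` of a difference of
#' `log_binom` values yields probability 0 without any special-casing at
#' the call sites. This zero convention silently covers every boundary the
#' hypergeometric derivation leaves implicit (for instance
#' `N - 2 - n_p < n - 2` in the no-neighbor terms); it is a documented
#' numeric contract, not an error.
#'
#' @param a non-negative integer(s), the pool size.
#' @param k integer(s), the selection size.
#' @return Numeric vector: log C(a, k), with `-Inf` where the selection is
#'   impossible. Arguments recycle as usual.
#' @examples
#' log_binom(5, 2) # log(10)
#' log_binom(3, 5) # -Inf
#' @export
log_binom <- function(a, k) {
  if (any(a < 0)) stop("`a` must be non-negative", call. = FALSE)
  n <- max(length(a), length(k))
  a <- rep_len(a, n)
  k <- rep_len(k, n)
  out <- rep(-Inf, n)
  ok <- k >= 0 & k <= a
  out[ok] <- lgamma(a[ok] + 1) - lgamma(k[ok] + 1) - lgamma(a[ok] - k[ok] + 1)
  out
}

#' Probability that none of a point's neighbors enter the subset
#'
#' Given that point p is in the random size-n subset S, the other n - 1
#' members are drawn uniformly from the remaining N - 1 points. If p has
#' n_p neighbors within the current radius, the chance that S avoids all of
#' them is the hypergeometric ratio C(N - 1 - n_p, n - 1) / C(N - 1, n - 1).
#'
#' @param n_p integer vector of neighbor counts, 0 <= n_p <= N - 1.
#' @param N total number of points.
#' @param n subset size, 1 <= n <= N.
#' @return Probabilities in \[0, 1\]; 1 when `n_p = 0` or `n = 1`, 0 when
#'   fewer than `n - 1` non-neighbors are available.
#' @export
prob_no_neighbor <- function(n_p, N, n) {
  stopifnot(length(N) == 1L, length(n) == 1L)
  if (N < 1L || n < 1L || n > N) stop("need 1 <= n <= N", call. = FALSE)
  if (any(n_p < 0 | n_p > N - 1)) stop("need 0 <= n_p <= N - 1", call. = FALSE)
  exp(log_binom(N - 1 - n_p, n - 1) - log_binom(N - 1, n - 1))
}

#' Exact CSR mean of the subset G function
#'
#' The expectation of G_S(r) over all C(N, n) equally likely size-n subsets
#' of the observed locations:
#' E\[G_S(r)\] = (1/N) * sum_p \[1 - C(N-1-n_p, n-1) / C(N-1, n-1)\],
#' where n_p is the number of points within r of p. This is the
#' permutation-free, sample-specific CSR reference curve.
#'
#' @param counts an N x R neighbor-count matrix from [neighbor_counts()].
#' @param n subset size.
#' @return Length-R numeric vector of CSR means, in \[0, 1\] and
#'   non-decreasing along the radius axis. `n = 1` gives 0 everywhere (a
#'   single marked point has no same-mark neighbor at any radius).
#' @export
exact_mean_g <- function(counts, n) {
  counts <- as.matrix(counts)
  N <- nrow(counts)
  if (n > N) stop("subset size n = ", n, " exceeds N = ", N, call. = FALSE)
  if (n < 1L) stop("need n >= 1", call. = FALSE)
  denom <- log_binom(N - 1, n - 1)
  p0 <- exp(matrix(log_binom(N - 1 - counts, n - 1), N) - denom)
  colMeans(1 - p0)
}

#' Joint success probability for a pair of points
#'
#' E\[X_p X_q\] for p != q: the probability that both p and q are selected
#' into the random subset and both have at least one same-subset neighbor
#' within r. Two cases:
#' * direct neighbors (dist(p, q) < r): joint selection suffices, so
#'   E\[X_p X_q\] = C(N-2, n-2) / C(N, n);
#' * otherwise each must find a neighbor among the other n - 2 selected
#'   points, handled by inclusion-exclusion over "p finds none" / "q finds
#'   none", whose intersection is controlled by the shared-neighbor count
#'   n_pq (neighbors of both are avoided once, not twice).
#'
#' @param p,q point indices (1-based), `p != q`.
#' @param pair a [pair_structure()] at the radius of interest.
#' @param counts_at_r integer vector of n_p values at the same radius.
#' @param N total points.
#' @param n subset size, n >= 2.
#' @return A single probability in \[0, 1\].
#' @export
joint_success_prob <- function(p, q, pair, counts_at_r, N, n) {
  stopifnot(inherits(pair, "pair_structure"), p != q)
  if (n < 2L) stop("pairs require n >= 2", call. = FALSE)
  base <- exp(log_binom(N - 2, n - 2) - log_binom(N, n))
  if (pair$direct[p, q]) return(base)
  np <- counts_at_r[p]
  nq <- counts_at_r[q]
  npq <- pair$shared[p, q]
  denom <- log_binom(N - 2, n - 2)
  a <- exp(log_binom(N - 2 - np, n - 2) - denom)
  b <- exp(log_binom(N - 2 - nq, n - 2) - denom)
  cc <- exp(log_binom(N - 2 - (np + nq - npq), n - 2) - denom)
  min(max(base * (1 - a - b + cc), 0), 1)
}

#' Exact CSR mean and variance of the subset G function
#'
#' Computes, per radius, the exact mean and the exact variance of G_S(r)
#' over all size-n subsets:
#' E\[G^2\] = (1/n^2) (sum_p E\[X_p\] + 2 sum_\{p<q\} E\[X_p X_q\]) and
#' Var = E\[G^2\] - E\[G\]^2, with the pair expectations from
#' [joint_success_prob()]. The pair pass is O(N^2) per radius and is run
#' radius-by-radius, so memory stays O(N^2) regardless of grid length; a
#' runtime warning is emitted above `warn_threshold` points, where
#' permutation becomes the more practical null.
#'
#' @param pattern a [point_pattern()].
#' @param grid a [radius_grid()].
#' @param n subset size. `n <= 1` yields a degenerate G (identically 0):
#'   mean and variance are returned as 0 with a warning rather than an
#'   error, so batch pipelines survive samples with a single positive cell.
#' @param closed use d <= r instead of the default strict d < r.
#' @param method `"moment"` (default) computes Var = E\[G^2\] - E\[G\]^2;
#'   `"covariance"` the algebraically identical decomposition
#'   (1/n^2) sum_p Var\[X_p\] + (2/n^2) sum_\{p<q\} Cov\[X_p, X_q\]. The two
#'   agree to floating-point accuracy and serve as mutual cross-checks.
#' @param warn_threshold emit a cost warning when N exceeds this (default 250).
#' @return A `csr_result`: list with `radii`, `mean`, `variance`, `sd`,
#'   `n`, `N`. Variance is clamped to 0 when a tiny negative value (within
#'   1e-9) arises from cancellation; larger negatives raise an error.
#' @examples
#' pp <- point_pattern(cbind(runif(15), runif(15)), window = c(0, 1, 0, 1))
#' res <- exact_var_g(pp, radius_grid(seq(0, 0.25, length.out = 10)), n = 4)
#' res$variance
#' @export
exact_var_g <- function(pattern, grid, n, closed = FALSE,
                        method = c("moment", "covariance"),
                        warn_threshold = 250L) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid <- radius_grid(grid)
  method <- match.arg(method)
  N <- pattern$N
  n <- as.integer(n)
  if (n > N) stop("subset size n = ", n, " exceeds N = ", N, call. = FALSE)
  R <- length(grid)
  counts <- neighbor_counts(pattern, grid, closed = closed)
  mean_g <- exact_mean_g(counts, max(n, 1L))
  if (n <= 1L) {
    warning("n <= 1: G_S is identically 0, returning zero mean and variance",
            call. = FALSE)
    return(new_csr_result(grid, mean = rep(0, R), variance = rep(0, R),
                          n = n, N = N))
  }
  if (N > warn_threshold) {
    warning("exact variance is O(N^2) per radius; N = ", N, " exceeds ",
            warn_threshold, " points, permutation may be more practical",
            call. = FALSE)
  }
  D <- full_distance_matrix(pattern)
  lb_N2_n2 <- log_binom(N - 2, n - 2)
  base <- exp(lb_N2_n2 - log_binom(N, n)) # P(p and q both selected)
  variance <- numeric(R)
  for (k in seq_len(R)) {
    r <- grid[k]
    direct <- if (closed) D <= r else D < r
    A <- direct + 0
    shared <- crossprod(A)
    np <- counts[, k]
    # Case 2 inclusion-exclusion terms; impossible selections exp(-Inf) -> 0.
    # A point with np = N - 1 neighbors everyone, so all its pairs are
    # Case 1 and its (masked) term may be clamped into range.
    a <- exp(log_binom(N - 2 - pmin(np, N - 2L), n - 2) - lb_N2_n2)
    # np + nq - npq = size of the union of the two neighbor sets; for
    # non-direct pairs it is at most N - 2. Direct pairs can push it past
    # that, but their bracket is replaced by the Case 1 value below, so
    # clamp to keep the log-binomial argument in range.
    m <- pmin(outer(np, np, "+") - shared, N - 2L)
    cterm <- exp(matrix(log_binom(N - 2 - m, n - 2), N) - lb_N2_n2)
    bracket <- 1 - outer(a, rep(1, N)) - outer(rep(1, N), a) + cterm
    joint <- base * ifelse(direct, 1, pmin(pmax(bracket, 0), 1))
    diag(joint) <- 0
    EX <- (n / N) * (1 - exp(log_binom(N - 1 - np, n - 1) - log_binom(N - 1, n - 1)))
    if (method == "moment") {
      EG2 <- (sum(EX) + sum(joint)) / n^2 # sum(joint) = 2 * sum_{p<q}
      v <- EG2 - mean_g[k]^2
    } else {
      varX <- EX * (1 - EX)
      cov_pq <- joint - outer(EX, EX)
      diag(cov_pq) <- 0
      v <- (sum(varX) + sum(cov_pq)) / n^2
    }
    variance[k] <- v
  }
  neg <- variance < 0
  if (any(variance[neg] < -1e-9)) {
    stop("internal inconsistency: variance ", min(variance),
         " below the cancellation tolerance", call. = FALSE)
  }
  variance[neg] <- 0
  new_csr_result(grid, mean = mean_g, variance = variance, n = n, N = N)
}

#' Exact CSR summary (mean, optionally variance) for a pattern
#'
#' Convenience wrapper: computes the exact CSR mean and, unless disabled,
#' the exact variance on the same grid.
#'
#' @inheritParams exact_var_g
#' @param variance compute the O(N^2)-per-radius variance too (default TRUE).
#' @return A `csr_result` (variance and sd are `NA` when `variance = FALSE`).
#' @export
exact_csr <- function(pattern, grid, n, closed = FALSE, variance = TRUE,
                      warn_threshold = 250L) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid <- radius_grid(grid)
  if (variance && n >= 2L) {
    return(exact_var_g(pattern, grid, n, closed = closed,
                       warn_threshold = warn_threshold))
  }
  counts <- neighbor_counts(pattern, grid, closed = closed)
  if (n <= 1L) {
    warning("n <= 1: G_S is identically 0, returning zero mean and variance",
            call. = FALSE)
    return(new_csr_result(grid, rep(0, length(grid)), rep(0, length(grid)),
                          n = n, N = pattern$N))
  }
  m <- exact_mean_g(counts, n)
  new_csr_result(grid, m, variance = rep(NA_real_, length(grid)),
                 n = n, N = pattern$N)
}

new_csr_result <- function(grid, mean, variance, n, N) {
  structure(list(radii = grid, mean = mean, variance = variance,
                 sd = sqrt(pmax(variance, 0)), n = n, N = N),
            class = "csr_result")
}

#' @export
print.csr_result <- function(x, ...) {
  cat("Exact CSR for subset G(r): N =", x$N, ", n =", x$n, ",",
      length(x$radii), "radii\n")
  cat(sprintf("mean range [%.4g, %.4g]", min(x$mean), max(x$mean)))
  if (!anyNA(x$variance)) {
    cat(sprintf(", sd range [%.4g, %.4g]", min(x$sd), max(x$sd)))
  }
  cat("\n")
  invisible(x)
}
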