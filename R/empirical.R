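#' Observed subset G function
#'
#' The uncorrected empirical cumulative distribution of nearest
#' same-subset-neighbor distances: for each radius r, the fraction of
#' subset points having at least one other subset point strictly within r
#' (or within r inclusive when `closed`). No edge correction is applied —
#' the sample-specific CSR reference conditions on the same locations, so
#' edge effects cancel out of the comparison.
#'
#' @param pattern a [point_pattern()].
#' @param subset a [subset_spec()] carrying a mask (e.g. from
#'   [subset_from_marks()] or [assign_marks()]).
#' @param grid a [radius_grid()].
#' @param closed use d <= r instead of strict d < r.
#' @return A `g_estimate` of kind `"observed"`.
#' @export
observed_g <- function(pattern, subset, grid, closed = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(subset, "subset_spec"))
  grid <- radius_grid(grid)
  if (is.null(subset$mask)) {
    stop("subset has no mask; observed G needs the concrete marked points",
         call. = FALSE)
  }
  if (length(subset$mask) != pattern$N) {
    stop("mask length ", length(subset$mask), " does not match N = ",
         pattern$N, call. = FALSE)
  }
  idx <- which(subset$mask)
  nnd <- subset_nn_distances(pattern$coords, idx)
  g <- g_from_nnd(matrix(nnd, ncol = 1), grid, closed)[, 1]
  new_g_estimate(grid, g, kind = "observed")
}

# Nearest within-subset neighbor distance for each subset member
# (Inf when the subset has a single point).
subset_nn_distances <- function(coords, idx) {
  n <- length(idx)
  if (n == 1L) return(Inf)
  D <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
  diag(D) <- Inf
  apply(D, 1L, min)
}

# g values per radius from an n x M matrix of nearest-neighbor distances:
# returns an R x M matrix, column j = G curve of subset j.
g_from_nnd <- function(nnd, grid, closed) {
  n <- nrow(nnd)
  R <- length(grid)
  out <- matrix(0, R, ncol(nnd))
  for (k in seq_len(R)) {
    hit <- if (closed) nnd <= grid[k] else nnd < grid[k]
    out[k, ] <- colSums(hit) / n
  }
  out
}

# Nearest within-subset neighbor distances for many subsets at once.
# D: full N x N distance matrix (Inf diagonal); subsets: n x M index matrix.
# Vectorized over subsets via the choose(n, 2) within-subset pair patterns.
batch_nn_distances <- function(D, subsets) {
  n <- nrow(subsets)
  M <- ncol(subsets)
  if (n == 1L) return(matrix(Inf, 1L, M))
  pr <- utils::combn(n, 2L)
  P <- ncol(pr)
  i <- subsets[pr[1L, ], , drop = FALSE]
  j <- subsets[pr[2L, ], , drop = FALSE]
  pd <- matrix(D[cbind(as.vector(i), as.vector(j))], P, M)
  nnd <- matrix(Inf, n, M)
  for (pos in seq_len(n)) {
    rows <- which(pr[1L, ] == pos | pr[2L, ] == pos)
    nnd[pos, ] <- do.call(pmin, lapply(rows, function(rr) pd[rr, ]))
  }
  nnd
}

#' Permutation estimate of the CSR null for subset G
#'
#' The classical empirical null: repeatedly draw a uniform random size-n
#' subset of the observed locations (equivalent to shuffling marks),
#' compute its G curve, and summarize per radius by mean, sd, and a
#' 2.5/97.5% quantile envelope. The exact CSR mean of [exact_mean_g()] is
#' the limit of this estimate as the number of permutations grows; the
#' permutation route remains useful as a nonparametric envelope.
#'
#' @param pattern a [point_pattern()].
#' @param n subset size.
#' @param grid a [radius_grid()].
#' @param n_perm number of random subsets to draw.
#' @param seed mandatory integer seed: permutation irreproducibility is
#'   exactly the weakness this package exists to remove, so unseeded runs
#'   are not allowed. The caller's RNG state is left untouched.
#' @param closed use d <= r instead of strict d < r.
#' @param envelope_probs the two envelope quantiles (type-7 interpolation).
#' @return A `g_estimate` of kind `"permutation_mean"` with `sd`, `lower`,
#'   `upper`, and `n_replicates` filled.
#' @export
permuted_csr <- function(pattern, n, grid, n_perm = 1000L, seed,
                         closed = FALSE, envelope_probs = c(0.025, 0.975)) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid <- radius_grid(grid)
  N <- pattern$N
  n <- as.integer(n)
  if (n > N) stop("subset size n = ", n, " exceeds N = ", N, call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducible permutation runs",
                          call. = FALSE)
  D <- full_distance_matrix(pattern)
  subsets <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sort(sample.int(N, n)), integer(n))
  })
  subsets <- matrix(subsets, nrow = n)
  g <- g_from_nnd(batch_nn_distances(D, subsets), grid, closed)
  qs <- apply(g, 1L, stats::quantile, probs = envelope_probs,
              names = FALSE, type = 7)
  new_g_estimate(grid, rowMeans(g), kind = "permutation_mean",
                 sd = apply(g, 1L, stats::sd),
                 lower = qs[1L, ], upper = qs[2L, ],
                 n_replicates = as.integer(n_perm))
}

#' Exhaustive enumeration of all size-n subsets (ground truth)
#'
#' Visits every one of the C(N, n) subsets in lexicographic order,
#' averaging G_S(r) and accumulating its population variance per radius.
#' This is the definitional value that [exact_mean_g()] and
#' [exact_var_g()] reproduce in closed form, and the oracle the package
#' validates them against. Refuses to run when C(N, n) exceeds `cap`.
#'
#' Subsets are processed in chunks with a two-pass (mean, then centered
#' sum of squares) accumulation, so the variance does not suffer the
#' cancellation of a raw sum-of-squares update and memory stays modest.
#'
#' @param pattern a [point_pattern()].
#' @param n subset size.
#' @param grid a [radius_grid()].
#' @param cap refuse enumerations beyond this many subsets (default 200000).
#' @param closed use d <= r instead of strict d < r.
#' @return A list with `mean` (a `g_estimate` of kind `"enumeration_mean"`),
#'   `variance` (per-radius population variance over all subsets), and
#'   `n_subsets` (= C(N, n)).
#' @export
brute_force_csr <- function(pattern, n, grid, cap = 200000L, closed = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid <- radius_grid(grid)
  N <- pattern$N
  n <- as.integer(n)
  if (n < 1L || n > N) stop("need 1 <= n <= N", call. = FALSE)
  n_subsets <- choose(N, n)
  if (n_subsets > cap) {
    stop("C(", N, ", ", n, ") = ", format(n_subsets, big.mark = ","),
         " subsets exceeds the enumeration cap of ", format(cap, big.mark = ","),
         call. = FALSE)
  }
  D <- full_distance_matrix(pattern)
  subsets <- utils::combn(N, n) # lexicographic order
  M <- ncol(subsets)
  R <- length(grid)
  chunk <- 20000L
  starts <- seq(1L, M, by = chunk)
  gsum <- numeric(R)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, M)
    g <- g_from_nnd(batch_nn_distances(D, subsets[, cols, drop = FALSE]),
                    grid, closed)
    gsum <- gsum + rowSums(g)
  }
  gmean <- gsum / M
  vsum <- numeric(R)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, M)
    g <- g_from_nnd(batch_nn_distances(D, subsets[, cols, drop = FALSE]),
                    grid, closed)
    vsum <- vsum + rowSums((g - gmean)^2)
  }
  list(mean = new_g_estimate(grid, gmean, kind = "enumeration_mean",
                             n_replicates = as.integer(M)),
       variance = vsum / M, # population variance: the subset distribution is
                            # fully enumerated, not sampled
       n_subsets = M)
}

#' Theoretical homogeneous-Poisson G curve
#'
#' The textbook nearest-neighbor cdf of a homogeneous Poisson process,
#' G(r) = 1 - exp(-lambda * pi * r^2). This is the naive stationary
#' baseline: in heterogeneous samples it overestimates clustering at small
#' radii and underestimates it at larger radii, which is the failure mode
#' the sample-specific CSR reference corrects. No edge correction is
#' applied (deliberately — it plays the naive-baseline role only).
#'
#' @param grid a [radius_grid()].
#' @param intensity points per unit area (lambda). When omitted, derived as
#'   `n / window area` from `pattern` and `n`.
#' @param pattern optional [point_pattern()] with a window, used to derive
#'   the intensity.
#' @param n optional subset size used with `pattern`'s window area.
#' @return A `g_estimate` of kind `"theoretical"`.
#' @export
theoretical_poisson_g <- function(grid, intensity = NULL, pattern = NULL, n = NULL) {
  grid <- radius_grid(grid)
  if (is.null(intensity)) {
    if (is.null(pattern) || is.null(pattern$window) || is.null(n)) {
      stop("supply `intensity`, or a pattern with a window plus `n` to derive it",
           call. = FALSE)
    }
    w <- pattern$window
    intensity <- n / ((w[2] - w[1]) * (w[4] - w[3]))
  }
  if (intensity <= 0) stop("intensity must be positive", call. = FALSE)
  g <- 1 - exp(-intensity * pi * as.numeric(grid)^2)
  new_g_estimate(grid, g, kind = "theoretical")
}

new_g_estimate <- function(grid, g, kind, sd = NULL, lower = NULL,
                           upper = NULL, n_replicates = NULL) {
  structure(list(radii = grid, g = g, kind = kind, sd = sd,
                 lower = lower, upper = upper, n_replicates = n_replicates),
            class = "g_estimate")
}

#' @export
print.g_estimate <- function(x, ...) {
  cat("G estimate (", x$kind, "): ", length(x$radii), " radii, range [",
      sprintf("%.4g", min(x$g)), ", ", sprintf("%.4g", max(x$g)), "]",
      sep = "")
  if (!is.null(x$n_replicates)) cat(", replicates:", x$n_replicates)
  cat("\n")
  invisible(x)
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
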