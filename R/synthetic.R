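#' Simulation configuration for synthetic point patterns
#'
#' Describes the test-bed patterns used to validate the CSR machinery:
#' uniform points in a rectangle (the canonical exhaustively-enumerable
#' fixture, e.g. 30 points of which 5 carry the mark of interest),
#' rectangles with rectangular holes (emulating tissue gaps and vessels —
#' the heterogeneity that breaks the stationary Poisson baseline), and
#' parent-offspring clusters. The seed is mandatory: identical configs
#' must reproduce identical patterns.
#'
#' @param N total number of points.
#' @param n number of positively marked points (0 <= n <= N).
#' @param window numeric `c(xmin, xmax, ymin, ymax)`, default unit square.
#' @param scenario `"uniform"`, `"hole"`, or `"clusters"`.
#' @param holes for `"hole"`: a matrix with rows `c(xmin, xmax, ymin, ymax)`
#'   (or a single such vector) of rectangles excluded from the support;
#'   each must lie strictly inside the window.
#' @param n_parents,offspring_sd for `"clusters"`: number of uniform parent
#'   points, and the Gaussian sd of offspring displacement (same units as
#'   the window).
#' @param seed integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(N, n, window = c(0, 1, 0, 1),
                              scenario = c("uniform", "hole", "clusters"),
                              holes = NULL, n_parents = 5L, offspring_sd = 0.05,
                              seed) {
  scenario <- match.arg(scenario)
  N <- as.integer(N)
  n <- as.integer(n)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (n < 0L || n > N) stop("need 0 <= n <= N", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  window <- as.numeric(window)
  if (length(window) != 4L || window[1] >= window[2] || window[3] >= window[4]) {
    stop("`window` must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  }
  if (scenario == "hole") {
    if (is.null(holes)) stop("scenario \"hole\" needs `holes`", call. = FALSE)
    holes <- matrix(as.numeric(holes), ncol = 4L, byrow = is.null(dim(holes)))
    for (i in seq_len(nrow(holes))) {
      h <- holes[i, ]
      if (h[1] >= h[2] || h[3] >= h[4]) {
        stop("hole ", i, " is degenerate", call. = FALSE)
      }
      if (h[1] <= window[1] && h[2] >= window[2] &&
          h[3] <= window[3] && h[4] >= window[4]) {
        stop("hole ", i, " covers the entire window: no support left",
             call. = FALSE)
      }
    }
  }
  structure(list(N = N, n = n, window = window, scenario = scenario,
                 holes = holes, n_parents = as.integer(n_parents),
                 offspring_sd = offspring_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic point pattern
#'
#' Deterministic given the config seed. `"uniform"` draws N iid uniform
#' points in the window; `"hole"` draws uniform points on the window minus
#' the hole rectangles by rejection sampling (exact, no area weighting);
#' `"clusters"` draws uniform parents, assigns each of the N offspring a
#' random parent and displaces it by an isotropic Gaussian, redrawing the
#' displacement until the point lands inside the window (truncation by
#' rejection). `offspring_sd = 0` collapses offspring onto their parents.
#'
#' @param config a [simulation_config()].
#' @return An unmarked [point_pattern()] with the config's window attached.
#' @export
generate_pattern <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  w <- config$window
  N <- config$N
  coords <- with_seed(config$seed, {
    switch(config$scenario,
      uniform = cbind(stats::runif(N, w[1], w[2]), stats::runif(N, w[3], w[4])),
      hole = {
        in_hole <- function(x, y) {
          hit <- rep(FALSE, length(x))
          for (i in seq_len(nrow(config$holes))) {
            h <- config$holes[i, ]
            hit <- hit | (x > h[1] & x < h[2] & y > h[3] & y < h[4])
          }
          hit
        }
        out <- matrix(NA_real_, 0L, 2L)
        tries <- 0L
        while (nrow(out) < N) {
          tries <- tries + 1L
          if (tries > 10000L) {
            stop("rejection sampling failed: holes leave almost no support",
                 call. = FALSE)
          }
          m <- max(N - nrow(out), 1L) * 2L
          x <- stats::runif(m, w[1], w[2])
          y <- stats::runif(m, w[3], w[4])
          keep <- !in_hole(x, y)
          out <- rbind(out, cbind(x[keep], y[keep]))
        }
        out[seq_len(N), , drop = FALSE]
      },
      clusters = {
        px <- stats::runif(config$n_parents, w[1], w[2])
        py <- stats::runif(config$n_parents, w[3], w[4])
        parent <- sample.int(config$n_parents, N, replace = TRUE)
        x <- numeric(N)
        y <- numeric(N)
        for (i in seq_len(N)) {
          repeat {
            xi <- px[parent[i]] + stats::rnorm(1, sd = config$offspring_sd)
            yi <- py[parent[i]] + stats::rnorm(1, sd = config$offspring_sd)
            if (xi >= w[1] && xi <= w[2] && yi >= w[3] && yi <= w[4]) break
          }
          x[i] <- xi
          y[i] <- yi
        }
        cbind(x, y)
      })
  })
  point_pattern(coords, window = w)
}

#' Randomly mark n of the N points positive
#'
#' Draws a uniformly random size-n subset of the pattern's points — the
#' CSR null's marking mechanism made concrete. Deterministic given `seed`.
#'
#' @param pattern a [point_pattern()].
#' @param n number of points to mark positive (0 <= n <= N; n = 0 gives an
#'   all-false mask with `n` recorded as 0).
#' @param seed integer seed.
#' @return A [subset_spec()] with a mask of the drawn subset.
#' @export
assign_marks <- function(pattern, n, seed) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- as.integer(n)
  if (n < 0L || n > pattern$N) {
    stop("need 0 <= n <= N = ", pattern$N, call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  mask <- rep(FALSE, pattern$N)
  if (n > 0L) {
    idx <- with_seed(seed, sample.int(pattern$N, n))
    mask[idx] <- TRUE
    subset_spec(n, mask)
  } else {
    structure(list(n = 0L, mask = mask), class = "subset_spec")
  }
}
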