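#' Marked 2D point patterns
#'
#' A `point_pattern` is the full set of N observed locations in a sample
#' (all cells, all individuals), optionally carrying a mark (phenotype,
#' species) per point and an axis-aligned rectangular observation window.
#' The CSR machinery in this package conditions on these locations: the
#' null model assigns marks at random to them, so the window is only
#' needed by the synthetic generator and the homogeneous-Poisson baseline.
#'
#' Coordinates are strictly 2D Euclidean; the exact subset-CSR formulas do
#' not extend to 3D and inputs carrying a third coordinate are rejected at
#' the reader level. Units (pixels, microns) are opaque — they must simply
#' match between coordinates and radii.
#'
#' @param coords numeric N x 2 matrix (or data frame) of x, y locations.
#' @param marks optional length-N vector of point labels.
#' @param window optional numeric vector `c(xmin, xmax, ymin, ymax)`; when
#'   present all points must lie inside it (inclusive).
#' @return An object of class `point_pattern`: a list with elements
#'   `coords`, `marks` (possibly `NULL`), `window` (possibly `NULL`), `N`.
#' @examples
#' pp <- point_pattern(cbind(runif(10), runif(10)), window = c(0, 1, 0, 1))
#' pp$N
#' @export
point_pattern <- function(coords, marks = NULL, window = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop("`coords` must be a numeric matrix with exactly 2 columns (x, y)",
         call. = FALSE)
  }
  if (nrow(coords) < 1L) stop("a point pattern needs at least one point", call. = FALSE)
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y"))
  N <- nrow(coords)
  if (!is.null(marks)) {
    if (length(marks) != N) {
      stop("`marks` must have one entry per point (", N, "), got ",
           length(marks), call. = FALSE)
    }
  }
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 4L || !all(is.finite(window)) ||
        window[1] >= window[2] || window[3] >= window[4]) {
      stop("`window` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax",
           call. = FALSE)
    }
    inside <- coords[, 1] >= window[1] & coords[, 1] <= window[2] &
      coords[, 2] >= window[3] & coords[, 2] <= window[4]
    if (!all(inside)) {
      stop(sum(!inside), " point(s) fall outside the stated window", call. = FALSE)
    }
    names(window) <- c("xmin", "xmax", "ymin", "ymax")
  }
  ndup <- sum(duplicated(coords))
  if (ndup > 0L) {
    warning(ndup, " duplicated coordinate(s): coincident points are mutual ",
            "neighbors at every r > 0", call. = FALSE)
  }
  structure(list(coords = coords, marks = marks, window = window, N = N),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("Marked planar point pattern:", x$N, "points\n")
  if (!is.null(x$marks)) {
    tab <- table(x$marks)
    cat("marks:", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
  }
  if (!is.null(x$window)) {
    cat(sprintf("window: [%g, %g] x [%g, %g]\n",
                x$window[1], x$window[2], x$window[3], x$window[4]))
  }
  invisible(x)
}

#' Subset specification: which n of the N points are "positive"
#'
#' Identifies the analyzed subset S — typically the points carrying the
#' phenotype of interest. Either a concrete mask (an observed marking) or
#' just the size n (for null computations, which only need n).
#'
#' @param n integer subset size, 1 <= n <= N when `N` is known.
#' @param mask optional logical vector selecting the observed subset; its
#'   number of `TRUE` entries must equal `n`.
#' @return An object of class `subset_spec` with elements `n` and `mask`.
#' @export
subset_spec <- function(n, mask = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
    if (sum(mask) != n) {
      stop("`mask` selects ", sum(mask), " points but n = ", n, call. = FALSE)
    }
  }
  structure(list(n = n, mask = mask), class = "subset_spec")
}

#' @export
print.subset_spec <- function(x, ...) {
  cat("Subset of size n =", x$n,
      if (is.null(x$mask)) "(no mask)" else paste0("of N = ", length(x$mask)), "\n")
  invisible(x)
}

#' Radius grid for evaluating G(r)
#'
#' @param radii strictly increasing numeric vector of non-negative radii,
#'   in the same length units as the point coordinates.
#' @return An object of class `radius_grid` (a validated numeric vector).
#' @examples
#' radius_grid(seq(0, 0.25, length.out = 100))
#' @export
radius_grid <- function(radii) {
  radii <- as.numeric(radii)
  if (length(radii) < 1L || !all(is.finite(radii))) {
    stop("`radii` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (radii[1] < 0) stop("radii must be non-negative", call. = FALSE)
  if (length(radii) > 1L && any(diff(radii) <= 0)) {
    stop("radii must be strictly increasing", call. = FALSE)
  }
  structure(radii, class = "radius_grid")
}

#' Default radius grid for a pattern
#'
#' 100 evenly spaced radii from 0 to one quarter of the shorter window
#' side; when the pattern has no window, to the maximum nearest-neighbor
#' distance among all points (so the grid always spans radii at which G
#' reaches 1 for the full set).
#'
#' @param pattern a [point_pattern()].
#' @param length.out number of radii.
#' @return A [radius_grid()].
#' @export
default_radius_grid <- function(pattern, length.out = 100L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.null(pattern$window)) {
    w <- pattern$window
    rmax <- min(w[2] - w[1], w[4] - w[3]) / 4
  } else {
    if (pattern$N < 2L) stop("cannot derive a radius grid from a single point without a window",
                             call. = FALSE)
    D <- full_distance_matrix(pattern)
    rmax <- max(apply(D, 1L, min))
    if (rmax <= 0) rmax <- 1 # all points coincident; any positive scale works
  }
  radius_grid(seq(0, rmax, length.out = length.out))
}

# Pairwise Euclidean distances with +Inf diagonal, so that strict or closed
# radius comparisons never count a point as its own neighbor.
full_distance_matrix <- function(pattern) {
  D <- as.matrix(stats::dist(pattern$coords))
  dimnames(D) <- NULL
  diag(D) <- Inf
  D
}
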