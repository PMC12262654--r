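#' Per-point neighbor counts at each radius
#'
#' For each point p and grid radius r, counts the other points of the full
#' pattern lying within distance r of p (strictly closer by default). This
#' n_p is the only per-point quantity the exact CSR mean needs.
#'
#' Two internal paths compute the same counts: a full distance matrix for
#' small patterns and a cell-list (grid binning) pass per radius for large
#' ones, which keeps memory at O(N) instead of O(N^2). The crossover is an
#' internal constant; both paths return identical integers and `method`
#' can force either for cross-checking.
#'
#' @param pattern a [point_pattern()].
#' @param grid a [radius_grid()].
#' @param closed if `TRUE`, count neighbors at distance exactly r too
#'   (d <= r); the default is the strict d < r convention used throughout
#'   the package.
#' @param method `"auto"` (default), `"dense"`, or `"cells"`.
#' @return An N x R integer matrix, `counts[p, k]` = number of q != p with
#'   dist(p, q) < radii\[k\] (or <= when `closed`).
#' @examples
#' pp <- point_pattern(cbind(c(0, 1), c(0, 0)))
#' neighbor_counts(pp, radius_grid(c(0.5, 1, 1.5)))
#' @export
neighbor_counts <- function(pattern, grid, closed = FALSE,
                            method = c("auto", "dense", "cells")) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid <- radius_grid(grid)
  method <- match.arg(method)
  N <- pattern$N
  if (method == "auto") {
    method <- if (N > .dense_crossover) "cells" else "dense"
  }
  R <- length(grid)
  if (method == "dense") {
    D <- full_distance_matrix(pattern)
    counts <- matrix(0L, N, R)
    for (k in seq_len(R)) {
      counts[, k] <- as.integer(rowSums(if (closed) D <= grid[k] else D < grid[k]))
    }
  } else {
    counts <- vapply(seq_len(R), function(k) {
      count_within_radius_cells(pattern$coords, grid[k], closed)
    }, integer(N))
    counts <- matrix(as.integer(counts), N, R)
  }
  counts
}

# Crossover (in points) between the dense distance-matrix path and the
# cell-list path; patterns above this would need >32 MB for the matrix.
.dense_crossover <- 2000L

# Fixed-radius neighbor counting via cell lists: bin points into square
# cells of side r, then for each occupied cell compare its members against
# the members of the 3x3 block of cells around it. O(N * local density).
count_within_radius_cells <- function(coords, r, closed = FALSE) {
  N <- nrow(coords)
  counts <- integer(N)
  if (r < 0) return(counts)
  if (r == 0) {
    if (!closed) return(counts)
    # d <= 0 means exactly coincident points
    key <- paste(coords[, 1], coords[, 2], sep = "\r")
    return(as.integer(ave(rep(1L, N), key, FUN = sum)) - 1L)
  }
  cx <- as.integer(floor(coords[, 1] / r))
  cy <- as.integer(floor(coords[, 2] / r))
  nx <- max(cx) - min(cx) + 3L # pad one cell each side so neighbor keys exist
  key <- (cx - min(cx) + 1L) + nx * (cy - min(cy) + 1L)
  members <- split(seq_len(N), key)
  occupied <- as.integer(names(members))
  for (cell in names(members)) {
    idx <- members[[cell]]
    k <- as.integer(cell)
    neigh_keys <- c(k - nx - 1L, k - nx, k - nx + 1L,
                    k - 1L,      k,      k + 1L,
                    k + nx - 1L, k + nx, k + nx + 1L)
    cand <- unlist(members[as.character(neigh_keys[neigh_keys %in% occupied])],
                   use.names = FALSE)
    dx <- outer(coords[idx, 1], coords[cand, 1], "-")
    dy <- outer(coords[idx, 2], coords[cand, 2], "-")
    d2 <- dx * dx + dy * dy
    within <- if (closed) d2 <= r * r else d2 < r * r
    # subtract the self-comparison (distance 0, always within for r > 0)
    counts[idx] <- as.integer(rowSums(within)) - 1L
  }
  counts
}

#' Pairwise neighbor structure at a single radius
#'
#' Computes, for one radius r, the direct-neighbor indicator
#' `direct[p, q]` = (dist(p, q) < r) and the shared-neighbor counts
#' `shared[p, q]` = number of points s (excluding p and q) within r of both.
#' These are the pair quantities the exact variance needs; they are
#' computed one radius at a time so memory stays O(N^2) however long the
#' radius grid is.
#'
#' @param pattern a [point_pattern()] with at least two points.
#' @param r a single radius.
#' @inheritParams neighbor_counts
#' @return A list of class `pair_structure` with `direct` (N x N logical,
#'   diagonal `FALSE`), `shared` (N x N integer, diagonal 0), and `r`.
#' @export
pair_structure <- function(pattern, r, closed = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$N < 2L) stop("pair structure needs at least two points", call. = FALSE)
  stopifnot(length(r) == 1L, is.finite(r), r >= 0)
  D <- full_distance_matrix(pattern)
  direct <- if (closed) D <= r else D < r # diagonal FALSE via Inf diagonal
  A <- direct + 0
  shared <- crossprod(A) # [p,q] = # s with s~p and s~q; s != p, q by zero diagonal of A
  diag(shared) <- 0
  storage.mode(shared) <- "integer"
  structure(list(direct = direct, shared = shared, r = r),
            class = "pair_structure")
}
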