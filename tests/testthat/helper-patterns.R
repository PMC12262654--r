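# Shared fixtures and brute-force oracles. All fixtures are generated in
# code from fixed seeds; the oracles are deliberately naive (double/triple
# loops over the distance matrix, full subset enumeration) and independent
# of the package's computational paths.

unit_square_pattern <- function(N, seed) {
  generate_pattern(simulation_config(N = N, n = 0, seed = seed))
}

# O(N^2 R) neighbor counts straight from the definition
bf_neighbor_counts <- function(coords, radii, closed = FALSE) {
  N <- nrow(coords)
  out <- matrix(0L, N, length(radii))
  for (p in seq_len(N)) {
    for (q in seq_len(N)) {
      if (p == q) next
      d <- sqrt(sum((coords[p, ] - coords[q, ])^2))
      for (k in seq_along(radii)) {
        hit <- if (closed) d <= radii[k] else d < radii[k]
        if (hit) out[p, k] <- out[p, k] + 1L
      }
    }
  }
  out
}

# O(N^3) shared-neighbor counts straight from the definition
bf_shared_counts <- function(coords, r, closed = FALSE) {
  N <- nrow(coords)
  d <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))
  within <- function(a, b) if (closed) d(a, b) <= r else d(a, b) < r
  out <- matrix(0L, N, N)
  for (p in seq_len(N)) for (q in seq_len(N)) {
    if (p == q) next
    for (s in seq_len(N)) {
      if (s == p || s == q) next
      if (within(s, p) && within(s, q)) out[p, q] <- out[p, q] + 1L
    }
  }
  out
}

# G_S(r) curve of one explicit subset, straight from the definition
bf_subset_g <- function(coords, idx, radii, closed = FALSE) {
  n <- length(idx)
  sapply(radii, function(r) {
    hits <- vapply(idx, function(p) {
      any(vapply(setdiff(idx, p), function(q) {
        d <- sqrt(sum((coords[p, ] - coords[q, ])^2))
        if (closed) d <= r else d < r
      }, logical(1)))
    }, logical(1))
    mean(hits)
  })
}

write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
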