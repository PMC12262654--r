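#' Read a marked point table from CSV
#'
#' Expects a comma-separated file with a header row (UTF-8). Column names
#' for the coordinates and the optional mark are configurable; row order is
#' preserved as point index order, so masks built from marks refer to input
#' rows. Files carrying a `z` column are rejected: the subset-CSR formulas
#' are only valid in the plane.
#'
#' @param path path to a CSV file.
#' @param x_col,y_col names of the coordinate columns (defaults `"x"`, `"y"`).
#' @param mark_col optional name of a mark/phenotype column.
#' @return A [point_pattern()] with `N` = number of data rows.
#' @export
read_points <- function(path, x_col = "x", y_col = "y", mark_col = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("input file has no data rows: ", path, call. = FALSE)
  if ("z" %in% names(df)) {
    stop("input has a `z` column; only 2D point patterns are supported ",
         "(drop the third coordinate explicitly if the data are planar)",
         call. = FALSE)
  }
  for (col in c(x_col, y_col, mark_col)) {
    if (!col %in% names(df)) {
      stop("column `", col, "` not found in ", path,
           " (columns present: ", paste(names(df), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  parse_coord <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("column `", col, "` is not a finite number at data row ", bad[1],
           " (value: \"", df[[col]][bad[1]], "\")", call. = FALSE)
    }
    v
  }
  coords <- cbind(parse_coord(x_col), parse_coord(y_col))
  marks <- if (!is.null(mark_col)) as.character(df[[mark_col]]) else NULL
  point_pattern(coords, marks = marks)
}

#' Build a subset mask from a mark label
#'
#' Marks the points whose label equals `positive_label` as the analyzed
#' subset S (e.g. the CD8+ cells among all cells).
#'
#' @param pattern a marked [point_pattern()].
#' @param positive_label the mark value defining the positive subset.
#' @return A [subset_spec()] with `n` = number of matching points and a mask
#'   aligned with the pattern's point order.
#' @export
subset_from_marks <- function(pattern, positive_label) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.null(pattern$marks)) {
    stop("pattern has no marks; supply `mark_col` when reading", call. = FALSE)
  }
  labels <- unique(pattern$marks)
  if (!positive_label %in% labels) {
    stop("label \"", positive_label, "\" not present in marks ",
         "(available: ", paste(labels, collapse = ", "), ")", call. = FALSE)
  }
  mask <- pattern$marks == positive_label
  n <- sum(mask)
  if (n == 0L) stop("no points carry label \"", positive_label, "\"", call. = FALSE)
  subset_spec(n, mask)
}

#' Assemble the per-radius result table
#'
#' One row per radius; always carries the CSR columns, plus observed-G and
#' test columns when supplied. All vectors must share the radius-grid
#' length.
#'
#' @param csr a `csr_result` from [exact_csr()] / [exact_var_g()].
#' @param observed optional `g_estimate` from [observed_g()].
#' @param test optional `csr_test_result` from [csr_test()].
#' @return A data frame with columns `r`, optionally `g_observed`,
#'   `csr_mean`, `csr_var`, `csr_sd`, and optionally `z`, `p_value`,
#'   `band_lower`, `band_upper`.
#' @export
result_table <- function(csr, observed = NULL, test = NULL) {
  stopifnot(inherits(csr, "csr_result"))
  R <- length(csr$radii)
  out <- data.frame(r = as.numeric(csr$radii))
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "g_estimate"))
    if (length(observed$g) != R || !isTRUE(all.equal(as.numeric(observed$radii),
                                                     as.numeric(csr$radii)))) {
      stop("observed G and CSR result were computed on different radius grids",
           call. = FALSE)
    }
    out$g_observed <- observed$g
  }
  out$csr_mean <- csr$mean
  out$csr_var <- csr$variance
  out$csr_sd <- csr$sd
  if (!is.null(test)) {
    stopifnot(inherits(test, "csr_test_result"))
    if (length(test$z) != R) {
      stop("test result length does not match the radius grid", call. = FALSE)
    }
    out$z <- test$z
    out$p_value <- test$p
    out$band_lower <- test$band_lower
    out$band_upper <- test$band_upper
  }
  out
}

#' Write a result table to CSV at full double precision
#'
#' Numbers are written with 17 significant digits so a read-back reproduces
#' the doubles bit-exactly.
#'
#' @param result a data frame as produced by [result_table()] (any data
#'   frame of equal-length numeric columns is accepted).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(result, path) {
  if (!is.data.frame(result)) stop("`result` must be a data frame", call. = FALSE)
  lens <- vapply(result, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("result columns have unequal lengths: ",
         paste(names(result), lens, sep = "=", collapse = ", "), call. = FALSE)
  }
  fmt <- result
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write result table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a point pattern as the standard point CSV
#'
#' @param pattern a [point_pattern()].
#' @param path output CSV path.
#' @param mark_col name for the mark column when the pattern is marked.
#' @return Invisibly, `path`.
#' @export
write_points <- function(pattern, path, mark_col = "mark") {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(x = sprintf("%.17g", pattern$coords[, 1]),
                   y = sprintf("%.17g", pattern$coords[, 2]))
  if (!is.null(pattern$marks)) df[[mark_col]] <- pattern$marks
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
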