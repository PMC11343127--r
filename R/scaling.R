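# Fold-change standardization ahead of ontology-level aggregation.
# Abundance FCs are range scaled — centered on the mean, divided by the
# span — so a value reflects relative change within the dataset's full
# dynamic range. Turnover FCs are auto scaled (z-scored with the sample
# standard deviation), which damps outliers from noisier rate estimates
# while keeping small coherent shifts visible.

.check_scalable <- function(x, what) {
  x_ok <- x[is.finite(x)]
  if (length(x_ok) < 2) {
    stop("Need at least two finite values to ", what, " scale.", call. = FALSE)
  }
  x_ok
}

#' Range-scale fold changes
#'
#' Centers on the mean and divides by the range: `(x - mean(x)) /
#' (max(x) - min(x))`. The output has mean 0 and spread (max minus min)
#' exactly 1. Non-finite entries propagate as `NA` and are excluded from
#' the summary statistics.
#'
#' @param x Numeric vector of fold changes with at least two distinct
#'   finite values.
#' @return Numeric vector of scaled values.
#' @examples
#' range_scale(c(1, 2, 3, 6))
#' @export
range_scale <- function(x) {
  x_ok <- .check_scalable(x, "range")
  rng <- max(x_ok) - min(x_ok)
  if (rng == 0) {
    stop("Degenerate input: all values identical, range is zero.", call. = FALSE)
  }
  (x - mean(x_ok)) / rng
}

#' Auto-scale (z-score) fold changes
#'
#' Centers on the mean and divides by the sample standard deviation
#' (denominator n - 1). The output has mean 0 and sample standard
#' deviation 1.
#'
#' @inheritParams range_scale
#' @return Numeric vector of scaled values.
#' @examples
#' auto_scale(c(1, 2, 3))
#' @export
auto_scale <- function(x) {
  x_ok <- .check_scalable(x, "auto")
  s <- stats::sd(x_ok)
  if (s == 0) {
    stop("Degenerate input: all values identical, standard deviation is zero.",
         call. = FALSE)
  }
  (x - mean(x_ok)) / s
}

#' Summary statistics backing a scaling transform
#'
#' @inheritParams range_scale
#' @return One-row tibble with `mean`, `sd` (sample standard deviation),
#'   `min`, `max` over the finite values.
#' @export
scaling_summary <- function(x) {
  x_ok <- x[is.finite(x)]
  tibble::tibble(
    mean = mean(x_ok),
    sd = stats::sd(x_ok),
    min = min(x_ok),
    max = max(x_ok)
  )
}
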