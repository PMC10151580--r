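# Two-tailed critical values for Dixon's r10 ("Q") statistic, n = 3..30,
# at confidence levels 90%, 95%, 99% (Rorabacher 1991, Anal. Chem. 63:139).
.dixon_crit_table <- matrix(
  c(
    # n,   90%,   95%,   99%
    3, 0.941, 0.970, 0.994,
    4, 0.765, 0.829, 0.926,
    5, 0.642, 0.710, 0.821,
    6, 0.560, 0.625, 0.740,
    7, 0.507, 0.568, 0.680,
    8, 0.468, 0.526, 0.634,
    9, 0.437, 0.493, 0.598,
    10, 0.412, 0.466, 0.568,
    11, 0.392, 0.444, 0.542,
    12, 0.376, 0.426, 0.522,
    13, 0.361, 0.410, 0.503,
    14, 0.349, 0.396, 0.488,
    15, 0.338, 0.384, 0.475,
    16, 0.329, 0.374, 0.463,
    17, 0.320, 0.365, 0.452,
    18, 0.313, 0.356, 0.442,
    19, 0.306, 0.349, 0.433,
    20, 0.300, 0.342, 0.425,
    21, 0.295, 0.337, 0.418,
    22, 0.290, 0.331, 0.411,
    23, 0.285, 0.326, 0.404,
    24, 0.281, 0.321, 0.399,
    25, 0.277, 0.317, 0.393,
    26, 0.273, 0.312, 0.388,
    27, 0.269, 0.308, 0.384,
    28, 0.266, 0.305, 0.380,
    29, 0.263, 0.301, 0.376,
    30, 0.260, 0.298, 0.372
  ),
  ncol = 4L, byrow = TRUE,
  dimnames = list(NULL, c("n", "0.9", "0.95", "0.99"))
)

#' Critical value of Dixon's Q statistic
#'
#' Tabulated two-tailed critical value of the r10 (gap/range) statistic for
#' `n` observations at a given confidence level.
#'
#' @param n Number of observations, 3 to 30.
#' @param confidence One of 0.90, 0.95, 0.99.
#' @return The critical value.
#' @export
dixon_critical <- function(n, confidence = 0.99) {
  if (!confidence %in% c(0.90, 0.95, 0.99))
    .tri_error("triomics_input",
               "confidence must be one of 0.90, 0.95, 0.99")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 3 || n > 30)
    .tri_error("triomics_input", "n out of range: Dixon table covers n = 3..30")
  .dixon_crit_table[.dixon_crit_table[, "n"] == n, as.character(confidence)][[1L]]
}

#' Dixon's Q outlier test
#'
#' Classic single-outlier screen for very small samples: on the sorted
#' values, `q_high = (x(n) - x(n-1)) / (x(n) - x(1))` tests the largest value
#' and `q_low = (x(2) - x(1)) / (x(n) - x(1))` tests the smallest; the larger
#' of the two is compared with the tabulated two-tailed critical value for
#' `(n, confidence)`. At most one value is flagged per call; the test is
#' applied once, without iterative re-testing after removal.
#'
#' Sorting is stable by value then sample ID; if `q_low` equals `q_high` the
#' high side is the one tested.
#'
#' @param values Numeric vector, optionally named with sample IDs
#'   (unnamed vectors get positional IDs); `NA`s are dropped. 3 to 30
#'   non-missing values required, with a strictly positive range.
#' @param confidence Confidence level, one of 0.90, 0.95, 0.99
#'   (default 0.99, the conventional strict level for irreplaceable
#'   post-mortem samples).
#' @param factor,layer Optional identifiers carried through for reporting.
#' @return An object of class `"dixon_result"`: a list with `factor`,
#'   `layer`, `n`, `q_low`, `q_high`, `q_crit`, `outlier_sample` (the
#'   flagged sample ID, or `""`), and `is_outlier`.
#' @examples
#' # post-mortem intervals (hours) of a six-subject cohort: not an outlier
#' dixon_q(c(15, 16.5, 17, 8, 4, 42), confidence = 0.99)
#' dixon_q(c(1, 2, 3, 4, 100), confidence = 0.99)  # 100 flagged
#' @export
dixon_q <- function(values, confidence = 0.99,
                    factor = NA_character_, layer = NA_character_) {
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  keep <- !is.na(values)
  values <- as.numeric(values[keep]); ids <- ids[keep]
  n <- length(values)
  if (n < 3L || n > 30L)
    .tri_error("triomics_input",
               sprintf("n out of range: %d values (Dixon table covers 3..30)", n))
  ord <- order(values, ids)
  v <- values[ord]; ids <- ids[ord]
  rng <- v[n] - v[1L]
  if (rng <= 0)
    .tri_error("triomics_degenerate", "degenerate values: zero range")
  q_low <- (v[2L] - v[1L]) / rng
  q_high <- (v[n] - v[n - 1L]) / rng
  q_crit <- dixon_critical(n, confidence)
  q_max <- max(q_low, q_high)
  is_outlier <- q_max >= q_crit
  side_high <- q_high >= q_low   # tie tests the high side
  res <- list(factor = factor, layer = layer, n = as.integer(n),
              q_low = q_low, q_high = q_high, q_crit = q_crit,
              outlier_sample = if (is_outlier) {
                if (side_high) ids[n] else ids[1L]
              } else "",
              is_outlier = is_outlier)
  class(res) <- "dixon_result"
  res
}

#' @export
print.dixon_result <- function(x, ...) {
  cat(sprintf("Dixon's Q test%s (n = %d): q_low = %.4f, q_high = %.4f, critical = %.3f\n",
              if (is.na(x$factor)) "" else paste0(" for ", x$factor),
              x$n, x$q_low, x$q_high, x$q_crit))
  cat(if (x$is_outlier)
        sprintf("  outlier: sample %s\n", x$outlier_sample)
      else "  no outlier flagged\n")
  invisible(x)
}
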