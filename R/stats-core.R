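#' @keywords internal
#' @noRd
.tri_error <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "triomics_error")))
}

# thresholds are quoted truncated (not rounded) at 5 decimals, so a printed
# threshold never exceeds the exact one
.fmt_rcrit <- function(r) sprintf("%.5f", trunc(r * 1e5) / 1e5)

#' Pearson correlation with exact small-sample significance
#'
#' Computes the product-moment correlation of two numeric vectors on
#' pairwise-complete positions, together with the quantities a small-sample
#' correlation test needs: the pairwise-complete sample count `n`, degrees of
#' freedom `df = n - 2`, the t statistic `t = |r| sqrt(n-2) / sqrt(1-r^2)`,
#' and — when a two-sided level `alpha` is supplied — the critical `|r|` at
#' `(alpha, df)` and a significance flag `|r| >= r_crit`.
#'
#' With only a handful of samples per factor (post-mortem cohorts routinely
#' have 4-6), p-values are less informative than the exact threshold the
#' fixed alpha implies, so the result carries the threshold rather than a
#' p-value.
#'
#' @param x,y Numeric vectors of equal length; `NA`s in either vector drop
#'   that position from the computation.
#' @param alpha Optional two-sided significance level in (0, 1). When `NULL`
#'   (default) no threshold or flag is attached.
#' @param factor_a,factor_b,layer_a,layer_b Optional identifiers carried
#'   through to the result for reporting.
#' @return An object of class `"cor_result"`: a list with elements
#'   `factor_a`, `layer_a`, `factor_b`, `layer_b`, `n`, `df`, `r`, `t`,
#'   `alpha`, `r_crit`, `significant`.
#' @examples
#' pearson_r(1:6, c(2, 1, 4, 3, 6, 5))$r          # 14.5 / 17.5
#' pearson_r(1:6, c(2, 1, 4, 3, 6, 5), alpha = 0.01)$significant
#' @seealso [critical_thresholds()], [t_from_r()], [partial_r()]
#' @export
pearson_r <- function(x, y, alpha = NULL,
                      factor_a = "x", factor_b = "y",
                      layer_a = NA_character_, layer_b = NA_character_) {
  if (length(x) != length(y))
    .tri_error("triomics_input", "x and y must have the same length")
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 3L)
    .tri_error("triomics_insufficient_overlap",
               sprintf("insufficient overlap: %d complete pairs (need >= 3)", n))
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    .tri_error("triomics_degenerate",
               "degenerate factor: zero variance on the complete pairs")
  r <- stats::cor(xs, ys)
  r <- max(-1, min(1, r))
  df <- n - 2L
  t <- if (abs(r) >= 1) Inf else abs(r) * sqrt(df) / sqrt(1 - r^2)
  res <- list(factor_a = factor_a, layer_a = layer_a,
              factor_b = factor_b, layer_b = layer_b,
              n = as.integer(n), df = as.integer(df), r = r, t = t,
              alpha = NA_real_, r_crit = NA_real_, significant = NA)
  if (!is.null(alpha)) {
    th <- critical_thresholds(alpha, df)
    res$alpha <- alpha
    res$r_crit <- th$r_crit
    res$significant <- abs(r) >= th$r_crit
  }
  class(res) <- "cor_result"
  res
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: %s [%s] vs %s [%s]\n",
              x$factor_a, x$layer_a, x$factor_b, x$layer_b))
  cat(sprintf("  r = %.5f  (n = %d, df = %d, t = %.3f)\n", x$r, x$n, x$df, x$t))
  if (!is.na(x$alpha))
    cat(sprintf("  two-sided alpha = %g: critical |r| = %s -> %s\n",
                x$alpha, .fmt_rcrit(x$r_crit),
                if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' t statistic of a correlation coefficient
#'
#' `t = |r| sqrt(n - 2) / sqrt(1 - r^2)`, the Student t statistic of a
#' Pearson coefficient `r` observed on `n` paired samples, with `n - 2`
#' degrees of freedom.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Number of paired samples, `n >= 3`.
#' @return The nonnegative t statistic.
#' @examples
#' t_from_r(0.91719, 6)   # ~ 4.604
#' t_from_r(0.5, 6)       # 1 / sqrt(0.75)
#' @export
t_from_r <- function(r, n) {
  if (!is.numeric(r) || !is.numeric(n) || length(r) != 1L || length(n) != 1L)
    .tri_error("triomics_input", "r and n must be numeric scalars")
  if (n < 3)
    .tri_error("triomics_input", "n must be >= 3")
  if (abs(r) > 1)
    .tri_error("triomics_input", "|r| must not exceed 1")
  if (abs(r) == 1)
    .tri_error("triomics_infinite_t",
               "infinite t: |r| = 1 has an unbounded t statistic")
  abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Critical t and critical |r| for a correlation test
#'
#' Inverts the correlation t-test at a two-sided level `alpha` and `df`
#' degrees of freedom: `t_crit` is the upper `alpha/2` quantile of Student's
#' t with `df` degrees of freedom and `r_crit = t_crit / sqrt(t_crit^2 + df)`
#' is the smallest `|r|` reaching significance. At `alpha = 0.01`, `df = 4`
#' (six samples) this gives `t_crit = 4.604`, `r_crit = 0.91719`; at `df = 2`
#' (four samples) `r_crit` exceeds 0.99, which is why factors sharing only
#' four samples essentially cannot reach significance.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param df Degrees of freedom (`n - 2`), a positive integer.
#' @return A list with elements `t_crit` and `r_crit`.
#' @examples
#' critical_thresholds(0.01, 4)  # t ~ 4.604, r ~ 0.91719
#' critical_thresholds(0.01, 2)  # r ~ 0.99005
#' @export
critical_thresholds <- function(alpha, df) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    .tri_error("triomics_input", "alpha must be a number in (0, 1)")
  if (!is.numeric(df) || length(df) != 1L || is.na(df) ||
      df < 1 || df != round(df))
    .tri_error("triomics_input", "df must be a positive integer")
  t_crit <- stats::qt(1 - alpha / 2, df = df)
  list(t_crit = t_crit, r_crit = t_crit / sqrt(t_crit^2 + df))
}

#' First-order partial correlation from three marginal coefficients
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / (sqrt(1 - r_xz^2) sqrt(1 - r_yz^2))`: the
#' correlation between x and y after removing the linear effect of z. It
#' equals the correlation of the least-squares residuals of x on z and of
#' y on z, and is symmetric in x and y.
#'
#' @param r_xy,r_xz,r_yz Marginal Pearson coefficients, all in `[-1, 1]`,
#'   with `|r_xz| < 1` and `|r_yz| < 1` (a controlled variable collinear
#'   with x or y leaves the partial undefined).
#' @return The partial correlation coefficient, clamped to `[-1, 1]`.
#' @examples
#' partial_r(0.5, 0, 0)        # uncorrelated control: unchanged
#' partial_r(0.72, 0.9, 0.8)   # full mediation: 0
#' @export
partial_r <- function(r_xy, r_xz, r_yz) {
  v <- c(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v) || any(abs(v) > 1))
    .tri_error("triomics_input", "all three coefficients must lie in [-1, 1]")
  if (abs(r_xz) == 1 || abs(r_yz) == 1)
    .tri_error("triomics_collinear",
               "controlled variable collinear with x or y (|r| = 1)")
  out <- (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))
  max(-1, min(1, out))
}

#' Partial correlation of data vectors
#'
#' Convenience wrapper: computes the three marginal coefficients on the
#' triple-complete positions of `x`, `y`, `z` and applies [partial_r()].
#'
#' @param x,y,z Numeric vectors of equal length; positions missing in any
#'   vector are dropped from all three.
#' @return A list of class `"partial_result"` with the marginals `r_xy`,
#'   `r_xz`, `r_yz`, the partial `r_partial`, and `n`.
#' @export
partial_r_data <- function(x, y, z) {
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  if (sum(keep) < 4L)
    .tri_error("triomics_insufficient_overlap",
               sprintf("insufficient overlap: %d complete triples (need >= 4)",
                       sum(keep)))
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    .tri_error("triomics_degenerate", "degenerate factor: zero variance")
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  structure(list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz,
                 r_partial = partial_r(r_xy, r_xz, r_yz),
                 n = as.integer(sum(keep))),
            class = "partial_result")
}
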