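#' All-pairs cross-layer correlation screen
#'
#' Correlates every factor of one layer against every factor of another,
#' using pairwise-complete observations, and flags each pair against the
#' critical `|r|` derived for that pair's own degrees of freedom — a factor
#' with missing samples faces a stricter threshold (at four shared samples,
#' two degrees of freedom, the 1% level requires `|r| > 0.99`). No
#' multiple-testing correction is applied: error control rests on the strict
#' per-pair level, and the number of tests performed is reported so users
#' can apply their own.
#'
#' @param dataset A `harmonized_dataset`.
#' @param layer_a,layer_b Labels of the two layers to cross.
#' @param alpha Two-sided significance level (default 0.01).
#' @return An object of class `"layer_screen"`: a list with `layer_pair`,
#'   `alpha`, `results` (data frame: `factor_a`, `factor_b`, `n`, `df`, `r`,
#'   `t`, `r_crit`, `significant`) and `skipped` (data frame of untestable
#'   pairs with reasons). Every factor pair lands in exactly one of the two.
#' @export
cross_layer_screen <- function(dataset, layer_a, layer_b, alpha = 0.01) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  if (!layer_a %in% names(dataset$layers))
    .tri_error("triomics_reference", sprintf("unknown layer '%s'", layer_a))
  if (!layer_b %in% names(dataset$layers))
    .tri_error("triomics_reference", sprintf("unknown layer '%s'", layer_b))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .tri_error("triomics_input", "alpha must be in (0, 1)")
  A <- dataset$layers[[layer_a]]$values
  B <- dataset$layers[[layer_b]]$values
  fa <- rownames(A); fb <- rownames(B)

  res_rows <- vector("list", 0L); skip_rows <- vector("list", 0L)
  complete <- !anyNA(A) && !anyNA(B)
  if (complete && ncol(A) >= 3L) {
    # fast path: one shared n, vectorized correlation
    sd_a <- apply(A, 1L, stats::sd); sd_b <- apply(B, 1L, stats::sd)
    ok_a <- sd_a > 0; ok_b <- sd_b > 0
    n <- ncol(A); df <- n - 2L
    th <- critical_thresholds(alpha, df)
    if (any(ok_a) && any(ok_b)) {
      R <- stats::cor(t(A[ok_a, , drop = FALSE]), t(B[ok_b, , drop = FALSE]))
      R <- pmin(1, pmax(-1, R))
      grid <- expand.grid(a = fa[ok_a], b = fb[ok_b],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      rv <- as.vector(R)
      res_rows[[1L]] <- data.frame(
        factor_a = grid$a, factor_b = grid$b, n = n, df = df, r = rv,
        t = ifelse(abs(rv) >= 1, Inf, abs(rv) * sqrt(df) / sqrt(1 - rv^2)),
        r_crit = th$r_crit, significant = abs(rv) >= th$r_crit,
        stringsAsFactors = FALSE)
    }
    degen <- rbind(
      expand.grid(a = fa[!ok_a], b = fb, KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE),
      expand.grid(a = fa[ok_a], b = fb[!ok_b], KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE))
    if (nrow(degen) > 0L)
      skip_rows[[1L]] <- data.frame(factor_a = degen$a, factor_b = degen$b,
                                    reason = "degenerate", stringsAsFactors = FALSE)
  } else {
    th_cache <- list()
    for (i in fa) for (j in fb) {
      x <- A[i, ]; y <- B[j, ]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      if (n < 3L) {
        skip_rows[[length(skip_rows) + 1L]] <- data.frame(
          factor_a = i, factor_b = j, reason = "insufficient overlap",
          stringsAsFactors = FALSE)
        next
      }
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        skip_rows[[length(skip_rows) + 1L]] <- data.frame(
          factor_a = i, factor_b = j, reason = "degenerate",
          stringsAsFactors = FALSE)
        next
      }
      key <- as.character(n)
      if (is.null(th_cache[[key]])) th_cache[[key]] <- critical_thresholds(alpha, n - 2L)
      th <- th_cache[[key]]
      r <- max(-1, min(1, stats::cor(x[keep], y[keep])))
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        factor_a = i, factor_b = j, n = n, df = n - 2L, r = r,
        t = if (abs(r) >= 1) Inf else abs(r) * sqrt(n - 2) / sqrt(1 - r^2),
        r_crit = th$r_crit, significant = abs(r) >= th$r_crit,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(factor_a = character(), factor_b = character(), n = integer(),
               df = integer(), r = numeric(), t = numeric(), r_crit = numeric(),
               significant = logical())
  skipped <- if (length(skip_rows)) do.call(rbind, skip_rows) else
    data.frame(factor_a = character(), factor_b = character(), reason = character())
  # canonical ordering: layer_a factors then layer_b factors, input order
  results <- results[order(match(results$factor_a, fa), match(results$factor_b, fb)), ,
                     drop = FALSE]
  rownames(results) <- NULL
  structure(list(layer_pair = c(layer_a, layer_b), alpha = alpha,
                 results = results, skipped = skipped,
                 n_tests = nrow(results)),
            class = "layer_screen")
}

#' @export
print.layer_screen <- function(x, ...) {
  cat(sprintf("<layer_screen> %s x %s (alpha = %g, two-sided)\n",
              x$layer_pair[1], x$layer_pair[2], x$alpha))
  cat(sprintf("  %d pairs tested, %d significant, %d skipped\n",
              nrow(x$results), sum(x$results$significant), nrow(x$skipped)))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig) > 0L) {
    cat("  significant pairs:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s ~ %s: r = %.2f (n = %d, critical |r| = %s)\n",
                  sig$factor_a[i], sig$factor_b[i], sig$r[i], sig$n[i],
                  .fmt_rcrit(sig$r_crit[i])))
  }
  invisible(x)
}

.fmt5 <- function(x) ifelse(is.na(x), "NA", sprintf("%.5f", x))

#' Export a screen as heatmap-ready matrices
#'
#' Writes the screen's correlation coefficients as a rectangular delimited
#' matrix (rows = first layer's factors, columns = second layer's factors,
#' `NA` for untestable pairs, 5 decimal places) plus a companion matrix of
#' significance flags (`TRUE`/`FALSE`/`NA`) at `<path>` with `_flags`
#' inserted before the extension.
#'
#' @param screen A `layer_screen`.
#' @param path Output file path (tab-delimited).
#' @return Invisibly, the character paths written (r matrix, flags matrix).
#' @export
export_heatmap_matrix <- function(screen, path) {
  stopifnot(inherits(screen, "layer_screen"))
  if (nrow(screen$results) + nrow(screen$skipped) == 0L)
    .tri_error("triomics_input", "empty screen")
  fa <- unique(c(screen$results$factor_a, screen$skipped$factor_a))
  fb <- unique(c(screen$results$factor_b, screen$skipped$factor_b))
  R <- matrix(NA_real_, length(fa), length(fb), dimnames = list(fa, fb))
  S <- matrix(NA, length(fa), length(fb), dimnames = list(fa, fb))
  idx <- cbind(match(screen$results$factor_a, fa), match(screen$results$factor_b, fb))
  R[idx] <- screen$results$r
  S[idx] <- screen$results$significant
  write_mat <- function(m, p, fmt) {
    con <- file(p, open = "wb")  # binary mode: stable newlines across platforms
    on.exit(close(con))
    writeLines(paste(c("factor_id", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  }
  flags_path <- sub("(\\.[^.]*)?$", "_flags\\1", path)
  ok <- tryCatch({
    write_mat(R, path, .fmt5)
    write_mat(S, flags_path, function(v) ifelse(is.na(v), "NA", as.character(v)))
    TRUE
  }, error = function(e) .tri_error("triomics_io", conditionMessage(e)))
  invisible(c(path, flags_path))
}
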