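#' Trans-omics correlation and mediation analysis
#'
#' The package's main fitting function. Runs the full small-cohort
#' trans-omics procedure on a set of omics layers sharing samples:
#'
#' 1. harmonize all layers to the common samples (metadata order);
#' 2. Dixon's Q outlier screen per factor, at `q_confidence`;
#' 3. apply the outlier policy (default: blank flagged cells);
#' 4. all-pairs cross-layer correlation screens at the strict two-sided
#'    `alpha`, each pair judged against the critical `|r|` for its own
#'    pairwise-complete degrees of freedom;
#' 5. enumerate mutually significant cross-layer triads (three layers);
#' 6. first-order partial-correlation mediation profile per triad;
#' 7. covariate correlation and adjustment (CPeq dose, age at death) for
#'    the triad factors.
#'
#' @param layers A list of [omics_layer()] objects, a `triomics_cohort`, or
#'   an already-harmonized dataset.
#' @param metadata A `sample_metadata` data frame (ignored when `layers`
#'   carries its own).
#' @param alpha Two-sided significance level for the correlation screens
#'   (default 0.01).
#' @param q_confidence Dixon confidence level, one of 0.90/0.95/0.99
#'   (default 0.99).
#' @param outlier_policy `"drop-value"` (default), `"drop-factor"` or
#'   `"keep"`; see [apply_outlier_policy()].
#' @param covariates Covariates for the adjustment stage (default CPeq and
#'   AoD); `NULL` skips the stage.
#' @param drop_threshold,retain_threshold Mediation classification
#'   thresholds, see [mediation_profile()].
#' @return An object of class `"triomics"` with elements `dataset`
#'   (post-policy), `qc`, `screens` (one [cross_layer_screen()] result per
#'   layer pair), `triads`, `profiles` (one [mediation_profile()] per
#'   triad), `covariates`, `outlier_sensitivity` (correlations of flagged
#'   factors with and without their outliers), `thresholds` (critical t and
#'   `|r|` per degrees of freedom encountered), and `params`.
#' @examples
#' coh <- generate_cohort(synthetic_spec(seed = 7))
#' fit <- triomics(coh, covariates = c("CPeq", "AoD"))
#' print(fit)
#' @export
triomics <- function(layers, metadata = NULL, alpha = 0.01, q_confidence = 0.99,
                     outlier_policy = c("drop-value", "drop-factor", "keep"),
                     covariates = c("CPeq", "AoD"),
                     drop_threshold = 0.30, retain_threshold = 0.50) {
  outlier_policy <- match.arg(outlier_policy)
  if (!q_confidence %in% c(0.90, 0.95, 0.99))
    .tri_error("triomics_input", "q_confidence must be one of 0.90, 0.95, 0.99")
  if (inherits(layers, "triomics_cohort")) {
    metadata <- layers$metadata
    layers <- layers$layers
  }
  dataset <- if (inherits(layers, "harmonized_dataset")) layers
             else harmonize(layers, metadata)
  raw <- dataset

  qc <- dixon_screen(dataset, confidence = q_confidence)
  dataset <- apply_outlier_policy(dataset, qc, policy = outlier_policy)

  labels <- names(dataset$layers)
  pair_idx <- utils::combn(seq_along(labels), 2L)
  screens <- list()
  for (k in seq_len(ncol(pair_idx))) {
    a <- labels[pair_idx[1L, k]]; b <- labels[pair_idx[2L, k]]
    screens[[paste(a, b, sep = "|")]] <-
      cross_layer_screen(dataset, a, b, alpha = alpha)
  }

  triads <- NULL; profiles <- list(); cov_report <- NULL
  if (length(labels) == 3L) {
    triads <- find_triads(screens)
    if (nrow(triads) > 0L) {
      profiles <- lapply(seq_len(nrow(triads)), function(i)
        mediation_profile(dataset, triads$x[i], triads$y[i], triads$z[i],
                          layers = c(triads$layer_x[i], triads$layer_y[i],
                                     triads$layer_z[i]),
                          drop_threshold = drop_threshold,
                          retain_threshold = retain_threshold))
      if (!is.null(covariates)) {
        fs <- unique(c(triads$x, triads$y, triads$z))
        ls <- unlist(lapply(fs, function(f) {
          i <- which(triads$x == f | triads$y == f | triads$z == f)[1L]
          if (triads$x[i] == f) triads$layer_x[i]
          else if (triads$y[i] == f) triads$layer_y[i]
          else triads$layer_z[i]
        }))
        cov_report <- covariate_analysis(dataset, fs, layers = ls,
                                         covariates = covariates)
      }
    }
  }

  # sensitivity: correlations of outlier-carrying factors with and without
  # the flagged value (mirrors reporting a separate outlier-excluded pass)
  sens <- list()
  hits <- qc[qc$is_outlier, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    f <- hits$factor[i]; ly <- hits$layer[i]
    for (ol in setdiff(labels, ly)) {
      for (pf in rownames(dataset$layers[[ol]]$values)) {
        with_r <- tryCatch(pearson_r(raw$layers[[ly]]$values[f, ],
                                     raw$layers[[ol]]$values[pf, ], alpha = alpha),
                           triomics_error = function(e) NULL)
        wo_vals <- raw$layers[[ly]]$values[f, ]
        wo_vals[hits$outlier_sample[i]] <- NA_real_
        wo_r <- tryCatch(pearson_r(wo_vals, raw$layers[[ol]]$values[pf, ],
                                   alpha = alpha),
                         triomics_error = function(e) NULL)
        sens[[length(sens) + 1L]] <- data.frame(
          layer = ly, factor = f, partner_layer = ol, partner = pf,
          n_with = if (is.null(with_r)) NA_integer_ else with_r$n,
          r_with = if (is.null(with_r)) NA_real_ else with_r$r,
          n_without = if (is.null(wo_r)) NA_integer_ else wo_r$n,
          r_without = if (is.null(wo_r)) NA_real_ else wo_r$r,
          stringsAsFactors = FALSE)
      }
    }
  }
  sens <- if (length(sens)) do.call(rbind, sens) else NULL

  dfs <- sort(unique(unlist(lapply(screens, function(s) s$results$df))))
  thresholds <- do.call(rbind, lapply(dfs, function(d) {
    th <- critical_thresholds(alpha, d)
    data.frame(df = d, n = d + 2L, t_crit = th$t_crit, r_crit = th$r_crit)
  }))

  structure(list(call = match.call(), dataset = dataset, qc = qc,
                 screens = screens, triads = triads, profiles = profiles,
                 covariates = cov_report, outlier_sensitivity = sens,
                 thresholds = thresholds,
                 params = list(alpha = alpha, q_confidence = q_confidence,
                               outlier_policy = outlier_policy,
                               covariates = covariates,
                               drop_threshold = drop_threshold,
                               retain_threshold = retain_threshold)),
            class = "triomics")
}

#' @export
print.triomics <- function(x, ...) {
  cat("Trans-omics correlation analysis\n")
  cat(sprintf("  %d layers, %d common samples; alpha = %g, Dixon Q%d%%, policy '%s'\n",
              length(x$dataset$layers), length(x$dataset$common_samples),
              x$params$alpha, round(100 * x$params$q_confidence),
              x$params$outlier_policy))
  cat(sprintf("  outliers flagged: %d; screens: %d pairs tested, %d significant\n",
              sum(x$qc$is_outlier),
              sum(vapply(x$screens, function(s) nrow(s$results), integer(1))),
              sum(vapply(x$screens, function(s) sum(s$results$significant),
                         integer(1)))))
  if (!is.null(x$triads))
    cat(sprintf("  triads: %d mutually significant cross-layer triangle(s)\n",
                nrow(x$triads)))
  for (p in x$profiles)
    cat(sprintf("    %s / %s / %s -> %s\n",
                p$factors["x"], p$factors["y"], p$factors["z"], p$classification))
  invisible(x)
}

#' @export
summary.triomics <- function(object, ...) {
  print(object)
  cat("\nCritical thresholds (two-sided alpha =", object$params$alpha, "):\n")
  th <- object$thresholds
  for (i in seq_len(nrow(th)))
    cat(sprintf("  df = %d (n = %d): t_crit = %.3f, critical |r| = %s\n",
                th$df[i], th$n[i], th$t_crit[i], .fmt_rcrit(th$r_crit[i])))
  if (sum(object$qc$is_outlier) > 0L) {
    cat("\nDixon-flagged factors:\n")
    h <- object$qc[object$qc$is_outlier, ]
    for (i in seq_len(nrow(h)))
      cat(sprintf("  %s [%s]: sample %s (Q = %.3f >= %.3f)\n",
                  h$factor[i], h$layer[i], h$outlier_sample[i],
                  pmax(h$q_low[i], h$q_high[i]), h$q_crit[i]))
  }
  for (s in object$screens) print(s)
  if (!is.null(object$covariates)) print(object$covariates)
  invisible(object)
}

#' Extract the screened correlation table
#'
#' @param object A `triomics` fit.
#' @param ... Unused.
#' @return A long-format data frame of every tested cross-layer factor
#'   pair: layer and factor identities, `n`, `df`, `r`, `t`, `r_crit`,
#'   `significant`.
#' @export
coef.triomics <- function(object, ...) {
  do.call(rbind, lapply(names(object$screens), function(k) {
    s <- object$screens[[k]]
    if (nrow(s$results) == 0L) return(NULL)
    cbind(data.frame(layer_a = s$layer_pair[1], layer_b = s$layer_pair[2],
                     stringsAsFactors = FALSE),
          s$results)
  }))
}

#' Heatmap of one cross-layer screen
#'
#' @param x A `triomics` fit.
#' @param pair Name of the screen to draw (`"layerA|layerB"`); default the
#'   first.
#' @param ... Passed to [graphics::image()].
#' @export
plot.triomics <- function(x, pair = names(x$screens)[1], ...) {
  s <- x$screens[[pair]]
  if (is.null(s)) .tri_error("triomics_reference", sprintf("unknown screen '%s'", pair))
  fa <- unique(s$results$factor_a); fb <- unique(s$results$factor_b)
  R <- matrix(NA_real_, length(fa), length(fb), dimnames = list(fa, fb))
  R[cbind(match(s$results$factor_a, fa), match(s$results$factor_b, fb))] <- s$results$r
  op <- graphics::par(mar = c(6, 6, 3, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(fb), seq_along(fa), t(R), zlim = c(-1, 1),
                  col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("r: %s x %s", s$layer_pair[1], s$layer_pair[2]), ...)
  graphics::axis(1, seq_along(fb), fb, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(fa), fa, las = 2, cex.axis = 0.7)
  invisible(x)
}

.write_tsv <- function(df, path, num_fmt = .fmt5) {
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    cells <- vapply(df[i, ], function(v) {
      if (is.numeric(v) && !is.integer(v)) .fmt5(v)
      else if (is.na(v)) "NA" else as.character(v)
    }, character(1))
    writeLines(paste(cells, collapse = "\t"), con)
  }
}

.md_table <- function(df, digits = 2) {
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) ifelse(is.na(v), "NA", sprintf(paste0("%.", digits, "f"), v))
    else ifelse(is.na(v), "NA", as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Write the full report bundle of a fit
#'
#' Writes a deterministic, human-readable `report.md` plus machine-readable
#' TSVs: `qc_dixon.tsv`, long-form `correlations_<A>_<B>.tsv` and wide-form
#' `heatmap_<A>_<B>.tsv` (with a `_flags` companion) per layer pair,
#' `triads.tsv`, and `covariates.tsv`. Coefficients are printed at 2
#' decimals in report tables and 5 decimals in TSVs.
#'
#' @param fit A `triomics` fit.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to echo in the reproduction note.
#' @return Invisibly, the path of `report.md`.
#' @export
write_report <- function(fit, dir, seed = NULL) {
  stopifnot(inherits(fit, "triomics"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- fit$params
  lines <- c("# Trans-omics correlation analysis report", "",
             "## Parameters", "",
             sprintf("- two-sided alpha: %g", p$alpha),
             sprintf("- Dixon confidence: Q%d%%", round(100 * p$q_confidence)),
             sprintf("- outlier policy: %s", p$outlier_policy),
             sprintf("- mediation thresholds: drop < %.2f, retain >= %.2f",
                     p$drop_threshold, p$retain_threshold),
             sprintf("- covariates: %s",
                     if (is.null(p$covariates)) "none"
                     else paste(p$covariates, collapse = ", ")),
             sprintf("- common samples: %d (%s)",
                     length(fit$dataset$common_samples),
                     paste(fit$dataset$common_samples, collapse = ", ")),
             "", "## Critical thresholds per degrees of freedom", "")
  th <- fit$thresholds
  # truncated quoting gives 0.91719 at df = 4, alpha = 0.01
  th_df <- data.frame(df = th$df, n = th$n,
                      t_crit = sprintf("%.3f", th$t_crit),
                      r_crit = .fmt_rcrit(th$r_crit))
  lines <- c(lines, .md_table(th_df), "", "## Outlier screen (Dixon's Q)", "")
  .write_tsv(fit$qc, file.path(dir, "qc_dixon.tsv"))
  hits <- fit$qc[fit$qc$is_outlier, , drop = FALSE]
  if (nrow(hits) > 0L) {
    lines <- c(lines,
               sprintf("%d factor(s) flagged; policy '%s' applied.", nrow(hits),
                       p$outlier_policy), "",
               .md_table(hits[, c("layer", "factor", "n", "q_high", "q_crit",
                                  "outlier_sample")], digits = 3))
  } else {
    lines <- c(lines, "No outliers flagged.")
  }
  lines <- c(lines, "", "## Cross-layer correlation screens", "")
  for (k in names(fit$screens)) {
    s <- fit$screens[[k]]
    tag <- gsub("[^A-Za-z0-9_]+", "_", paste(s$layer_pair, collapse = "_"))
    .write_tsv(s$results, file.path(dir, sprintf("correlations_%s.tsv", tag)))
    export_heatmap_matrix(s, file.path(dir, sprintf("heatmap_%s.tsv", tag)))
    lines <- c(lines, sprintf("### %s x %s", s$layer_pair[1], s$layer_pair[2]), "",
               sprintf("%d pairs tested at alpha = %g (no multiplicity correction), %d significant, %d skipped.",
                       nrow(s$results), s$alpha, sum(s$results$significant),
                       nrow(s$skipped)), "")
    sig <- s$results[s$results$significant, , drop = FALSE]
    if (nrow(sig) > 0L)
      lines <- c(lines, .md_table(sig[, c("factor_a", "factor_b", "n", "r", "r_crit")]), "")
    else lines <- c(lines, "No pair exceeded the threshold.", "")
  }
  if (!is.null(fit$outlier_sensitivity)) {
    lines <- c(lines, "## Outlier sensitivity (correlations with vs without flagged value)", "",
               .md_table(fit$outlier_sensitivity), "")
  }
  lines <- c(lines, "## Mediation triads", "")
  if (!is.null(fit$triads) && nrow(fit$triads) > 0L) {
    tri_rows <- lapply(fit$profiles, function(pr)
      data.frame(x = pr$factors["x"], y = pr$factors["y"], z = pr$factors["z"],
                 n = pr$n,
                 r_xy = pr$marginals["r_xy"], r_xz = pr$marginals["r_xz"],
                 r_yz = pr$marginals["r_yz"],
                 r_xy.z = pr$partials["r_xy.z"], r_xz.y = pr$partials["r_xz.y"],
                 r_yz.x = pr$partials["r_yz.x"],
                 classification = pr$classification, stringsAsFactors = FALSE))
    tri_df <- do.call(rbind, tri_rows); rownames(tri_df) <- NULL
    .write_tsv(tri_df, file.path(dir, "triads.tsv"))
    lines <- c(lines, .md_table(tri_df), "")
  } else {
    lines <- c(lines, "No triads: no mutually significant cross-layer triangle closed.", "")
    .write_tsv(data.frame(x = character(), y = character(), z = character()),
               file.path(dir, "triads.tsv"))
  }
  lines <- c(lines, "## Covariate analysis", "")
  if (!is.null(fit$covariates)) {
    .write_tsv(fit$covariates$marginals, file.path(dir, "covariates.tsv"))
    .write_tsv(fit$covariates$partials, file.path(dir, "covariates_partials.tsv"))
    lines <- c(lines, "### Factor-covariate correlations", "",
               .md_table(fit$covariates$marginals), "",
               "### Factor-pair partials controlling each covariate", "",
               .md_table(fit$covariates$partials), "")
  } else {
    lines <- c(lines, "Not run.", "")
    .write_tsv(data.frame(factor = character(), covariate = character()),
               file.path(dir, "covariates.tsv"))
  }
  lines <- c(lines, "## Reproduction", "",
             sprintf("- seed: %s", if (is.null(seed)) "none (deterministic inputs)" else seed),
             sprintf("- triomics version: %s",
                     as.character(utils::packageVersion("triomics"))),
             sprintf("- R version: %s.%s", R.version$major, R.version$minor))
  con <- file(file.path(dir, "report.md"), open = "wb")
  writeLines(lines, con)
  close(con)
  invisible(file.path(dir, "report.md"))
}

#' Run the pipeline from files
#'
#' Thin end-to-end wrapper: reads the layer and metadata files, runs
#' [triomics()], and writes the report bundle plus a `run.log` echoing every
#' effective parameter and per-stage counts.
#'
#' @param layer_paths Named character vector: layer label -> file path.
#' @param metadata_path Metadata file path.
#' @param out Output directory.
#' @param alpha,q_confidence,outlier_policy,covariates,drop_threshold,retain_threshold
#'   Passed to [triomics()].
#' @param sep Field delimiter override for all input files (`NULL` infers
#'   per file from its extension).
#' @param seed Optional seed echoed into the report (the analysis itself is
#'   deterministic).
#' @return The `triomics` fit, invisibly.
#' @export
run_pipeline <- function(layer_paths, metadata_path, out,
                         alpha = 0.01, q_confidence = 0.99,
                         outlier_policy = "drop-value",
                         covariates = c("CPeq", "AoD"),
                         drop_threshold = 0.30, retain_threshold = 0.50,
                         sep = NULL, seed = NULL) {
  if (is.null(names(layer_paths)) || any(names(layer_paths) == ""))
    .tri_error("triomics_input", "layer_paths must be named label = path")
  log_lines <- c("triomics pipeline",
                 sprintf("parameters: alpha=%g q_confidence=%g outlier_policy=%s covariates=%s drop=%g retain=%g seed=%s",
                         alpha, q_confidence, outlier_policy,
                         if (is.null(covariates)) "none" else paste(covariates, collapse = ","),
                         drop_threshold, retain_threshold,
                         if (is.null(seed)) "none" else seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  layers <- stage("read", {
    lapply(seq_along(layer_paths), function(i)
      read_omics_layer(layer_paths[[i]], name = names(layer_paths)[i], sep = sep))
  })
  md <- stage("read", read_sample_metadata(metadata_path, sep = sep))
  for (i in seq_along(layers))
    log_lines <- c(log_lines, sprintf("read layer %s: %d factors x %d samples from %s",
                                      layers[[i]]$name, nrow(layers[[i]]$values),
                                      ncol(layers[[i]]$values), layer_paths[[i]]))
  log_lines <- c(log_lines, sprintf("read metadata: %d samples from %s",
                                    nrow(md), metadata_path))
  fit <- stage("analysis",
               triomics(layers, md, alpha = alpha, q_confidence = q_confidence,
                        outlier_policy = outlier_policy, covariates = covariates,
                        drop_threshold = drop_threshold,
                        retain_threshold = retain_threshold))
  log_lines <- c(log_lines,
                 sprintf("harmonized: %d common samples", length(fit$dataset$common_samples)),
                 sprintf("dixon screen: %d factors tested, %d flagged",
                         nrow(fit$qc), sum(fit$qc$is_outlier)),
                 vapply(fit$screens, function(s)
                   sprintf("screen %s x %s: %d tested, %d significant, %d skipped",
                           s$layer_pair[1], s$layer_pair[2], nrow(s$results),
                           sum(s$results$significant), nrow(s$skipped)), character(1)),
                 sprintf("triads: %d", if (is.null(fit$triads)) 0L else nrow(fit$triads)))
  stage("report", write_report(fit, out, seed = seed))
  con <- file(file.path(out, "run.log"), open = "wb")
  writeLines(log_lines, con)
  close(con)
  invisible(fit)
}
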