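.substream <- function(seed, k) {
  # deterministic per-component substreams from one root seed, kept in
  # 32-bit integer range; adding a layer never perturbs earlier layers
  as.integer((as.numeric(seed) + k * 99991) %% 2147483629)
}

#' Specify a synthetic multi-omics cohort
#'
#' Parameterizes a small case-control cohort measured on several omics
#' layers, with one planted cross-layer relationship whose ground truth is
#' recorded alongside the data. All factors are generated with unit
#' population variance, so the loadings are population correlations: under
#' the mediated structure `cor(x, z) = loading_a`, `cor(y, z) = loading_b`
#' and `cor(x, y) = loading_a * loading_b`.
#'
#' Structures: `"mediated"` (x and y, in the first two layers, both driven
#' by a mediator z written into the third layer), `"direct"` (y driven by x,
#' z independent), `"confounded"` (x and y both driven by the standardized
#' CPeq dose covariate), `"null"` (all factors independent).
#'
#' @param n_scz,n_con Group sizes (default 3 and 3, the classic post-mortem
#'   trans-omics design).
#' @param layer_sizes Named integer vector of factors per layer; the default
#'   `c(lipidomics = 2, transcriptomics = 7, proteomics = 17)` mirrors a
#'   2-lipid / 7-gene / 17-protein screen.
#' @param structure One of `"mediated"`, `"direct"`, `"confounded"`,
#'   `"null"`.
#' @param loading_a,loading_b Loadings of x and y on the driver, in
#'   (-1, 1); under unit-variance scaling these are population correlations.
#' @param noise_sd Residual standard deviation of the planted factors;
#'   `NULL` (default) uses `sqrt(1 - loading^2)` so planted factors have
#'   unit population variance.
#' @param group_shift Additive offset applied to planted factors of SCZ
#'   samples (default 0: a pure correlation structure with no group effect).
#' @param cpeq_range Range (mg/day) of the uniform chlorpromazine-equivalent
#'   dose drawn for SCZ samples; controls get 0.
#' @param missing_pattern Named list: factor ID -> character vector of
#'   sample IDs to blank to `NA` (emulates factors quantified on a subset of
#'   the cohort).
#' @param outlier Optional single-point outlier to inject after generation:
#'   a list with `factor`, `sample`, `magnitude` (in SDs of the factor's
#'   other values), or a list of such lists.
#' @param seed Root seed (integer); fully determines the cohort.
#' @return An object of class `"synthetic_spec"`.
#' @seealso [generate_cohort()]
#' @export
synthetic_spec <- function(n_scz = 3, n_con = 3,
                           layer_sizes = c(lipidomics = 2, transcriptomics = 7,
                                           proteomics = 17),
                           structure = c("mediated", "direct", "confounded", "null"),
                           loading_a = 0.95, loading_b = 0.95,
                           noise_sd = NULL, group_shift = 0,
                           cpeq_range = c(200, 1200),
                           missing_pattern = NULL, outlier = NULL, seed = 1L) {
  structure_kind <- match.arg(structure)
  if (n_scz < 0 || n_con < 0 || n_scz + n_con < 3)
    .tri_error("triomics_input", "need at least 3 samples in total")
  if (is.null(names(layer_sizes)) || anyDuplicated(names(layer_sizes)))
    .tri_error("triomics_input", "layer_sizes must have unique names")
  if (structure_kind != "null" && length(layer_sizes) < 3L)
    .tri_error("triomics_input",
               sprintf("'%s' structure plants one factor per layer and needs 3 layers",
                       structure_kind))
  if (abs(loading_a) >= 1 || abs(loading_b) >= 1)
    .tri_error("triomics_input", "loadings must lie in (-1, 1)")
  if (!is.null(noise_sd) && noise_sd <= 0)
    .tri_error("triomics_input", "noise_sd must be > 0")
  if (length(cpeq_range) != 2L || any(cpeq_range < 0) || diff(cpeq_range) < 0)
    .tri_error("triomics_input", "cpeq_range must be a nonnegative increasing pair")
  if (!is.null(outlier) && !is.null(outlier$factor)) outlier <- list(outlier)
  seed <- as.integer(seed)
  if (is.na(seed)) .tri_error("triomics_input", "seed must be an integer")
  structure(list(n_scz = as.integer(n_scz), n_con = as.integer(n_con),
                 layer_sizes = layer_sizes, structure = structure_kind,
                 loading_a = loading_a, loading_b = loading_b,
                 noise_sd = noise_sd, group_shift = group_shift,
                 cpeq_range = cpeq_range, missing_pattern = missing_pattern,
                 outlier = outlier, seed = seed),
            class = "synthetic_spec")
}

.layer_unit <- function(name) {
  switch(name,
         lipidomics = "signal intensity",
         transcriptomics = "FPKM",
         proteomics = "quantitative signal intensity",
         "arbitrary unit")
}

#' Generate a synthetic cohort from a specification
#'
#' Draws the metadata and all layer matrices deterministically from the
#' spec's root seed (per-component substreams: metadata, planted structure,
#' one per layer), plants the specified structure in the first factor of
#' each relevant layer, applies missingness, injects any requested
#' outliers, and returns the data together with a truth record from which
#' every planted relationship is recoverable.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `"triomics_cohort"`: `layers` (list of
#'   [omics_layer()]), `metadata` (`sample_metadata` data frame), `truth`
#'   (planted structure, loadings, residual SDs, outliers with original
#'   values, seed), and `spec`.
#' @examples
#' coh <- generate_cohort(synthetic_spec(seed = 42))
#' coh$truth$planted
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_scz + spec$n_con
  ids <- c(sprintf("S%02d", seq_len(spec$n_scz)),
           sprintf("C%02d", seq_len(spec$n_con)))
  dx <- rep(c("SCZ", "CON"), c(spec$n_scz, spec$n_con))

  set.seed(.substream(spec$seed, 1L))
  metadata <- data.frame(
    sample_id = ids,
    diagnosis = dx,
    age = sample(60:90, n, replace = TRUE),
    sex = sample(c("Male", "Female"), n, replace = TRUE),
    pmi = round(stats::runif(n, 4, 45), 1),
    doi = ifelse(dx == "SCZ", round(stats::runif(n, 20, 60)), 0),
    cpeq = ifelse(dx == "SCZ",
                  round(stats::runif(n, spec$cpeq_range[1], spec$cpeq_range[2])),
                  0),
    cause_of_death = "synthetic",
    stringsAsFactors = FALSE)
  class(metadata) <- c("sample_metadata", "data.frame")

  sd_a <- if (is.null(spec$noise_sd)) sqrt(1 - spec$loading_a^2) else spec$noise_sd
  sd_b <- if (is.null(spec$noise_sd)) sqrt(1 - spec$loading_b^2) else spec$noise_sd

  set.seed(.substream(spec$seed, 2L))
  planted <- NULL
  if (spec$structure == "mediated") {
    z <- stats::rnorm(n)
    x <- spec$loading_a * z + sd_a * stats::rnorm(n)
    y <- spec$loading_b * z + sd_b * stats::rnorm(n)
  } else if (spec$structure == "direct") {
    x <- stats::rnorm(n)
    y <- spec$loading_a * x + sd_a * stats::rnorm(n)
    z <- stats::rnorm(n)
  } else if (spec$structure == "confounded") {
    cstd <- as.vector(scale(metadata$cpeq))
    if (any(!is.finite(cstd)))
      .tri_error("triomics_degenerate", "CPeq constant: cannot plant a confounded structure")
    x <- spec$loading_a * cstd + sd_a * stats::rnorm(n)
    y <- spec$loading_b * cstd + sd_b * stats::rnorm(n)
    z <- stats::rnorm(n)
  }

  layer_names <- names(spec$layer_sizes)
  layers <- vector("list", length(layer_names)); names(layers) <- layer_names
  for (i in seq_along(layer_names)) {
    ln <- layer_names[i]; p <- spec$layer_sizes[[i]]
    set.seed(.substream(spec$seed, 10L + i))
    vals <- matrix(stats::rnorm(p * n), nrow = p, ncol = n,
                   dimnames = list(sprintf("%s_%02d", substr(ln, 1, 4), seq_len(p)),
                                   ids))
    layers[[ln]] <- omics_layer(vals, name = ln, unit = .layer_unit(ln))
  }
  if (spec$structure != "null") {
    pl <- function(i) rownames(layers[[i]]$values)[1L]
    shift <- ifelse(dx == "SCZ", spec$group_shift, 0)
    layers[[1L]]$values[1L, ] <- x + shift
    layers[[2L]]$values[1L, ] <- y + shift
    layers[[3L]]$values[1L, ] <- z + shift
    planted <- list(x = list(factor = pl(1), layer = layer_names[1]),
                    y = list(factor = pl(2), layer = layer_names[2]),
                    z = list(factor = pl(3), layer = layer_names[3]))
  }

  # per-factor missingness (e.g. a lipid quantified on only 4 of 6 subjects)
  if (!is.null(spec$missing_pattern)) {
    for (f in names(spec$missing_pattern)) {
      hit <- FALSE
      for (ln in layer_names) {
        if (f %in% rownames(layers[[ln]]$values)) {
          ss <- spec$missing_pattern[[f]]
          if (!all(ss %in% ids))
            .tri_error("triomics_validation",
                       sprintf("missing_pattern for '%s' names unknown sample(s)", f))
          layers[[ln]]$values[f, ss] <- NA_real_
          hit <- TRUE
        }
      }
      if (!hit)
        .tri_error("triomics_validation",
                   sprintf("missing_pattern names unknown factor '%s'", f))
    }
  }

  cohort <- structure(list(
    layers = layers, metadata = metadata,
    truth = list(structure = spec$structure, planted = planted,
                 loading_a = spec$loading_a, loading_b = spec$loading_b,
                 noise_sd_x = sd_a, noise_sd_y = sd_b,
                 group_shift = spec$group_shift, seed = spec$seed,
                 outliers = list()),
    spec = spec), class = "triomics_cohort")

  for (o in spec$outlier)
    cohort <- inject_outlier(cohort, o$factor, o$sample, o$magnitude)
  cohort
}

#' @export
print.triomics_cohort <- function(x, ...) {
  cat(sprintf("<triomics_cohort> %d SCZ + %d CON, structure '%s' (seed %d)\n",
              x$spec$n_scz, x$spec$n_con, x$truth$structure, x$truth$seed))
  for (l in x$layers) print(l)
  if (!is.null(x$truth$planted))
    cat(sprintf("  planted: x = %s, y = %s, z = %s\n",
                x$truth$planted$x$factor, x$truth$planted$y$factor,
                x$truth$planted$z$factor))
  invisible(x)
}

#' Inject a single-point outlier into a cohort
#'
#' Replaces one cell with `mean + magnitude * sd` of the factor's other
#' non-missing values and records the original value in the truth record,
#' so outlier-screening stages can be exercised against known ground truth.
#'
#' @param cohort A `triomics_cohort`.
#' @param factor Factor ID.
#' @param sample Sample ID.
#' @param magnitude Displacement in SDs of the factor's remaining values.
#' @return The modified cohort.
#' @export
inject_outlier <- function(cohort, factor, sample, magnitude) {
  stopifnot(inherits(cohort, "triomics_cohort"))
  hit <- NULL
  for (ln in names(cohort$layers))
    if (factor %in% rownames(cohort$layers[[ln]]$values)) hit <- ln
  if (is.null(hit))
    .tri_error("triomics_reference", sprintf("unknown factor '%s'", factor))
  if (!sample %in% colnames(cohort$layers[[hit]]$values))
    .tri_error("triomics_reference", sprintf("unknown sample '%s'", sample))
  v <- cohort$layers[[hit]]$values[factor, ]
  if (is.na(v[[sample]]))
    .tri_error("triomics_reference",
               sprintf("cell (%s, %s) is already missing", factor, sample))
  others <- v[names(v) != sample]
  others <- others[!is.na(others)]
  if (length(others) < 2L)
    .tri_error("triomics_input", "need at least 2 other values to scale the outlier")
  original <- v[[sample]]
  cohort$layers[[hit]]$values[factor, sample] <-
    mean(others) + magnitude * stats::sd(others)
  cohort$truth$outliers[[length(cohort$truth$outliers) + 1L]] <-
    list(factor = factor, layer = hit, sample = sample,
         magnitude = magnitude, original_value = original)
  cohort
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

#' Write a cohort to delimited files
#'
#' Writes one factor-by-sample TSV per layer (the format [read_omics_layer()]
#' reads), a metadata TSV ([read_sample_metadata()]'s format), and the truth
#' record as YAML. Output is byte-deterministic for a given cohort.
#'
#' @param cohort A `triomics_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "triomics_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (ln in names(cohort$layers)) {
    p <- file.path(dir, paste0(ln, ".tsv"))
    m <- cohort$layers[[ln]]$values
    con <- file(p, open = "wb");
    writeLines(paste(c("factor_id", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t"), con)
    close(con)
    paths[[ln]] <- p
  }
  mp <- file.path(dir, "metadata.tsv")
  md <- cohort$metadata
  con <- file(mp, open = "wb")
  writeLines(paste(names(md), collapse = "\t"), con)
  for (i in seq_len(nrow(md)))
    writeLines(paste(vapply(md[i, ], as.character, character(1)), collapse = "\t"), con)
  close(con)
  paths$metadata <- mp
  tp <- file.path(dir, "truth.yaml")
  con <- file(tp, open = "wb")
  writeLines(yaml::as.yaml(cohort$truth), con, sep = "")
  close(con)
  paths$truth <- tp
  invisible(paths)
}
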