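#' Construct an omics layer
#'
#' A layer is one omics modality's factor-by-sample matrix (lipid species,
#' genes, or proteins in rows; subjects in columns) with a label and a
#' free-text unit (signal intensity, FPKM, ...). Missing cells are `NA`.
#'
#' @param values Numeric matrix with unique row names (factor IDs) and unique
#'   column names (sample IDs).
#' @param name Layer label, e.g. `"lipidomics"`.
#' @param unit Free-text description of the values.
#' @return An object of class `"omics_layer"`.
#' @export
omics_layer <- function(values, name, unit = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .tri_error("triomics_format", "layer matrix needs factor row names and sample column names")
  if (anyDuplicated(rownames(values)))
    .tri_error("triomics_format",
               sprintf("duplicate factor IDs in layer '%s'", name))
  if (anyDuplicated(colnames(values)))
    .tri_error("triomics_format",
               sprintf("duplicate sample IDs in layer '%s'", name))
  structure(list(name = name, values = values, unit = unit),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer> %s: %d factors x %d samples%s\n",
              x$name, nrow(x$values), ncol(x$values),
              if (is.na(x$unit)) "" else paste0(" [", x$unit, "]")))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an omics layer table
#'
#' Reads a delimited factor-by-sample table: first column holds factor IDs,
#' remaining column headers are sample IDs, cells are numeric or the literal
#' token `NA`. The delimiter is inferred from the extension (`.csv` comma,
#' otherwise tab) and can be overridden.
#'
#' @param path File path.
#' @param name Layer label to attach.
#' @param unit Free-text unit.
#' @param sep Field delimiter; `NULL` (default) infers from the extension.
#' @return An [omics_layer()]; row and column order preserved.
#' @export
read_omics_layer <- function(path, name, unit = NA_character_, sep = NULL) {
  if (!file.exists(path))
    .tri_error("triomics_io", sprintf("file not found: %s", path))
  sep <- .infer_sep(path, sep)
  lines <- readLines(path)
  if (length(lines) < 2L)
    .tri_error("triomics_format", sprintf("%s: need a header and at least one factor row", path))
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    .tri_error("triomics_format",
               sprintf("%s: duplicate sample column header(s): %s", path,
                       paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  factors <- raw[[1L]]
  if (anyDuplicated(factors))
    .tri_error("triomics_format",
               sprintf("%s: duplicate factor ID(s): %s", path,
                       paste(unique(factors[duplicated(factors)]), collapse = ", ")))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("NA", "na", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    .tri_error("triomics_parse",
               sprintf("%s: non-numeric cell '%s' at factor '%s', sample '%s'",
                       path, cells[bad[1L, , drop = FALSE]],
                       factors[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(num) <- list(factors, samples)
  omics_layer(num, name = name, unit = unit)
}

.norm_diagnosis <- function(d) {
  u <- toupper(trimws(d))
  u[u %in% c("SCZ", "SCHIZOPHRENIA")] <- "SCZ"
  u[u %in% c("CON", "CONTROL", "CTRL")] <- "CON"
  bad <- setdiff(unique(u), c("SCZ", "CON"))
  if (length(bad) > 0L)
    .tri_error("triomics_format",
               sprintf("unrecognized diagnosis value(s): %s", paste(bad, collapse = ", ")))
  u
}

#' Read a sample metadata table
#'
#' Reads per-subject clinical covariates: `sample_id`, `diagnosis` (SCZ or
#' CON, case-insensitive; "schizophrenia"/"control" accepted), `age` (years
#' at death), `sex`, `pmi` (post-mortem interval, hours), `doi` (duration of
#' illness, years), `cpeq` (chlorpromazine-equivalent antipsychotic dose,
#' mg/day; 0 for controls by convention), and optionally `cause_of_death`.
#'
#' @param path File path (delimiter inferred from extension, overridable).
#' @param sep Field delimiter; `NULL` infers from the extension.
#' @return A data frame of class `"sample_metadata"`, one row per sample.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path))
    .tri_error("triomics_io", sprintf("file not found: %s", path))
  sep <- .infer_sep(path, sep)
  md <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  required <- c("sample_id", "diagnosis", "age", "sex", "pmi", "doi", "cpeq")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0L)
    .tri_error("triomics_format",
               sprintf("%s: missing required column(s): %s", path,
                       paste(missing_cols, collapse = ", ")))
  if (!"cause_of_death" %in% names(md)) md$cause_of_death <- NA_character_
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    .tri_error("triomics_format", sprintf("%s: duplicate sample_id", path))
  md$diagnosis <- .norm_diagnosis(md$diagnosis)
  for (col in c("age", "pmi", "doi", "cpeq")) {
    md[[col]] <- suppressWarnings(as.numeric(md[[col]]))
    if (any(md[[col]] < 0, na.rm = TRUE))
      .tri_error("triomics_validation", sprintf("%s: negative %s", path, col))
  }
  if (any(md$diagnosis == "CON" & !is.na(md$cpeq) & md$cpeq > 0))
    warning("control sample(s) with cpeq > 0: convention is 0 mg/day for CON",
            call. = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Harmonize omics layers to their common samples
#'
#' Restricts every layer to the samples present in all layers and in the
#' metadata, in metadata row order (the canonical sample order everywhere
#' downstream), and records per-factor available-sample counts.
#'
#' @param layers List of [omics_layer()] objects (at least two).
#' @param metadata A `sample_metadata` data frame.
#' @return An object of class `"harmonized_dataset"`: a list with `layers`
#'   (restricted, named by layer label), `metadata` (restricted),
#'   `common_samples`, and `availability` (per layer, a named integer vector
#'   of non-missing sample counts per factor).
#' @examples
#' \dontrun{
#' ds <- harmonize(list(lip, rna, prot), metadata)
#' }
#' @export
harmonize <- function(layers, metadata) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  if (length(layers) < 2L)
    .tri_error("triomics_input", "harmonize needs at least two layers")
  labels <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(labels))
    .tri_error("triomics_format", "duplicate layer labels")
  names(layers) <- labels
  sample_sets <- lapply(layers, function(l) colnames(l$values))
  common <- Reduce(intersect, sample_sets, metadata$sample_id)
  common <- metadata$sample_id[metadata$sample_id %in% common]
  if (length(common) == 0L)
    .tri_error("triomics_no_common_samples", "no common samples across layers and metadata")
  layers <- lapply(layers, function(l) {
    l$values <- l$values[, common, drop = FALSE]
    l
  })
  md <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  availability <- lapply(layers, function(l) rowSums(!is.na(l$values)))
  structure(list(layers = layers, metadata = md, common_samples = common,
                 availability = availability),
            class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat(sprintf("<harmonized_dataset> %d common samples (%s)\n",
              length(x$common_samples),
              paste(sprintf("%d %s", table(x$metadata$diagnosis)[c("SCZ", "CON")],
                            c("SCZ", "CON")), collapse = " / ")))
  for (l in x$layers)
    cat(sprintf("  %s: %d factors%s\n", l$name, nrow(l$values),
                if (any(x$availability[[l$name]] < length(x$common_samples)))
                  sprintf(" (%d with missing samples)",
                          sum(x$availability[[l$name]] < length(x$common_samples)))
                else ""))
  invisible(x)
}

#' Dixon outlier screen over a harmonized dataset
#'
#' Runs [dixon_q()] once per factor on its non-missing values pooled over
#' all common samples (cases and controls together, matching a whole-group
#' correlation analysis).
#'
#' @param dataset A `harmonized_dataset`.
#' @param confidence Dixon confidence level (default 0.99).
#' @return A data frame of class `"dixon_screen"` with one row per testable
#'   factor: `layer`, `factor`, `n`, `q_low`, `q_high`, `q_crit`,
#'   `outlier_sample`, `is_outlier`. Factors that cannot be tested (fewer
#'   than 3 values, zero range) are listed in the `"skipped"` attribute.
#' @export
dixon_screen <- function(dataset, confidence = 0.99) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  rows <- list(); skipped <- list()
  for (l in dataset$layers) {
    for (f in rownames(l$values)) {
      v <- l$values[f, ]
      res <- tryCatch(dixon_q(v, confidence = confidence, factor = f, layer = l$name),
                      triomics_error = function(e) e)
      if (inherits(res, "dixon_result")) {
        rows[[length(rows) + 1L]] <- data.frame(
          layer = l$name, factor = f, n = res$n, q_low = res$q_low,
          q_high = res$q_high, q_crit = res$q_crit,
          outlier_sample = res$outlier_sample, is_outlier = res$is_outlier,
          stringsAsFactors = FALSE)
      } else {
        skipped[[length(skipped) + 1L]] <- data.frame(
          layer = l$name, factor = f, reason = conditionMessage(res),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(layer = character(), factor = character(), n = integer(),
               q_low = numeric(), q_high = numeric(), q_crit = numeric(),
               outlier_sample = character(), is_outlier = logical())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "confidence") <- confidence
  class(out) <- c("dixon_screen", "data.frame")
  out
}

#' Apply an outlier-exclusion policy
#'
#' Given Dixon flags, either blanks the flagged cells (`"drop-value"`, the
#' default: the factor stays in the analysis with reduced per-factor
#' availability), removes the whole flagged factor (`"drop-factor"`), or
#' leaves the data untouched but records the flags for reporting (`"keep"`).
#'
#' @param dataset A `harmonized_dataset`.
#' @param flags A `dixon_screen` data frame (or a list of `dixon_result`
#'   objects); only rows with `is_outlier = TRUE` are acted on.
#' @param policy One of `"drop-value"`, `"drop-factor"`, `"keep"`.
#' @return The modified `harmonized_dataset`; flags acted on (or kept) are
#'   stored in its `outlier_flags` element.
#' @export
apply_outlier_policy <- function(dataset,
                                 flags,
                                 policy = c("drop-value", "drop-factor", "keep")) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  policy <- match.arg(policy)
  if (is.list(flags) && !is.data.frame(flags))
    flags <- do.call(rbind, lapply(flags, function(f)
      data.frame(layer = f$layer, factor = f$factor, n = f$n, q_low = f$q_low,
                 q_high = f$q_high, q_crit = f$q_crit,
                 outlier_sample = f$outlier_sample, is_outlier = f$is_outlier,
                 stringsAsFactors = FALSE)))
  hits <- flags[flags$is_outlier, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    ly <- hits$layer[i]; fa <- hits$factor[i]; sa <- hits$outlier_sample[i]
    if (!ly %in% names(dataset$layers) ||
        !fa %in% rownames(dataset$layers[[ly]]$values))
      .tri_error("triomics_reference",
                 sprintf("flag refers to unknown factor '%s' in layer '%s'", fa, ly))
    if (!sa %in% colnames(dataset$layers[[ly]]$values))
      .tri_error("triomics_reference",
                 sprintf("flag refers to unknown sample '%s'", sa))
    if (policy == "drop-value")
      dataset$layers[[ly]]$values[fa, sa] <- NA_real_
    else if (policy == "drop-factor")
      dataset$layers[[ly]]$values <-
        dataset$layers[[ly]]$values[rownames(dataset$layers[[ly]]$values) != fa, ,
                                    drop = FALSE]
  }
  dataset$availability <- lapply(dataset$layers,
                                 function(l) rowSums(!is.na(l$values)))
  dataset$outlier_flags <- hits
  dataset$outlier_policy <- policy
  dataset
}
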