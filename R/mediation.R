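.find_factor <- function(dataset, factor, layer = NULL) {
  if (!is.null(layer) && !is.na(layer)) {
    if (!layer %in% names(dataset$layers))
      .tri_error("triomics_reference", sprintf("unknown layer '%s'", layer))
    if (!factor %in% rownames(dataset$layers[[layer]]$values))
      .tri_error("triomics_reference",
                 sprintf("unknown factor '%s' in layer '%s'", factor, layer))
    return(list(values = dataset$layers[[layer]]$values[factor, ], layer = layer))
  }
  hits <- names(dataset$layers)[vapply(dataset$layers, function(l)
    factor %in% rownames(l$values), logical(1))]
  if (length(hits) == 0L)
    .tri_error("triomics_reference", sprintf("unknown factor '%s'", factor))
  if (length(hits) > 1L)
    .tri_error("triomics_reference",
               sprintf("factor '%s' present in several layers (%s); give the layer",
                       factor, paste(hits, collapse = ", ")))
  list(values = dataset$layers[[hits]]$values[factor, ], layer = hits)
}

#' Find mutually significant cross-layer triads
#'
#' Given the three pairwise screens of a three-layer dataset, returns every
#' triple (one factor per layer) whose three cross-layer correlations are
#' all flagged significant — the closed triangles that mediation profiling
#' then dissects.
#'
#' @param screens A list of exactly three [cross_layer_screen()] results
#'   covering the three distinct layer pairs.
#' @return A data frame, one row per triad, with columns `x`, `layer_x`,
#'   `y`, `layer_y`, `z`, `layer_z` (layers in lexicographic order, rows
#'   ordered lexicographically by factor). Zero rows if no triangle closes.
#' @export
find_triads <- function(screens) {
  if (!is.list(screens) || length(screens) != 3L ||
      !all(vapply(screens, inherits, logical(1), "layer_screen")))
    .tri_error("triomics_input", "screens must be a list of three layer_screen objects")
  pairs <- lapply(screens, function(s) sort(s$layer_pair))
  layers <- sort(unique(unlist(pairs)))
  if (length(layers) != 3L || anyDuplicated(vapply(pairs, paste, character(1), collapse = "|")))
    .tri_error("triomics_input",
               "screens must cover the three distinct pairs of three layers")
  # significant pair lookup in canonical (lexicographic layer) orientation
  sig <- list()
  for (s in screens) {
    key <- paste(sort(s$layer_pair), collapse = "|")
    res <- s$results[s$results$significant, , drop = FALSE]
    if (s$layer_pair[1] > s$layer_pair[2]) {
      res <- data.frame(factor_a = res$factor_b, factor_b = res$factor_a,
                        stringsAsFactors = FALSE)
    }
    sig[[key]] <- res[, c("factor_a", "factor_b"), drop = FALSE]
  }
  k12 <- paste(layers[1], layers[2], sep = "|")
  k13 <- paste(layers[1], layers[3], sep = "|")
  k23 <- paste(layers[2], layers[3], sep = "|")
  has <- function(tab, a, b) any(tab$factor_a == a & tab$factor_b == b)
  out <- list()
  p12 <- sig[[k12]]
  if (nrow(p12) > 0L) {
    for (i in seq_len(nrow(p12))) {
      f1 <- p12$factor_a[i]; f2 <- p12$factor_b[i]
      cand <- sig[[k13]]$factor_b[sig[[k13]]$factor_a == f1]
      for (f3 in cand)
        if (has(sig[[k23]], f2, f3))
          out[[length(out) + 1L]] <- data.frame(
            x = f1, layer_x = layers[1], y = f2, layer_y = layers[2],
            z = f3, layer_z = layers[3], stringsAsFactors = FALSE)
    }
  }
  triads <- if (length(out)) do.call(rbind, out) else
    data.frame(x = character(), layer_x = character(), y = character(),
               layer_y = character(), z = character(), layer_z = character())
  triads <- triads[order(triads$x, triads$y, triads$z), , drop = FALSE]
  rownames(triads) <- NULL
  triads
}

.classify_triad <- function(marginals, partials, drop_threshold, retain_threshold) {
  # marginals/partials named: r_xy, r_xz, r_yz / r_xy.z, r_xz.y, r_yz.x
  p <- abs(partials); m <- abs(marginals)
  fired <- c(
    `mediated-by-z` = p[["r_xy.z"]] < drop_threshold &&
      p[["r_xz.y"]] >= retain_threshold && p[["r_yz.x"]] >= retain_threshold,
    `mediated-by-y` = p[["r_xz.y"]] < drop_threshold &&
      p[["r_xy.z"]] >= retain_threshold && p[["r_yz.x"]] >= retain_threshold,
    `mediated-by-x` = p[["r_yz.x"]] < drop_threshold &&
      p[["r_xy.z"]] >= retain_threshold && p[["r_xz.y"]] >= retain_threshold)
  if (sum(fired) == 1L) return(names(fired)[fired])
  if (sum(fired) > 1L) return("indeterminate")
  # direct: every strongly correlated pair keeps a strong partial
  strong <- m >= retain_threshold
  partner <- c(r_xy = "r_xy.z", r_xz = "r_xz.y", r_yz = "r_yz.x")
  if (any(strong) && all(p[partner[names(m)[strong]]] >= retain_threshold))
    return("direct")
  "indeterminate"
}

#' Mediation profile of a cross-layer triad
#'
#' Computes, on the samples complete in all three factors, the three
#' marginal correlations and the three first-order partials (each pair
#' controlling the third factor), and classifies the triad. A pair whose
#' correlation collapses once the third factor is controlled
#' (`|partial| < drop_threshold`) while both remaining partials stay strong
#' (`>= retain_threshold`) indicates mediation by that third factor. No
#' significance test is attached to the partials — with a handful of samples
#' only coefficient magnitudes are compared.
#'
#' @param dataset A `harmonized_dataset`.
#' @param x,y,z Factor IDs, one per layer.
#' @param layers Optional character vector of length 3 naming the layers of
#'   `x`, `y`, `z`; resolved by search when omitted.
#' @param drop_threshold Partial magnitude below which a controlled pair
#'   counts as collapsed (default 0.30).
#' @param retain_threshold Partial magnitude at or above which a coefficient
#'   counts as retained (default 0.50).
#' @return An object of class `"triad_report"`: factors and layers,
#'   `n` (triple-complete sample count), `marginals` (`r_xy`, `r_xz`,
#'   `r_yz`), `partials` (`r_xy.z`, `r_xz.y`, `r_yz.x`), and
#'   `classification` (one of `mediated-by-x/y/z`, `direct`,
#'   `indeterminate`).
#' @export
mediation_profile <- function(dataset, x, y, z, layers = NULL,
                              drop_threshold = 0.30, retain_threshold = 0.50) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  fx <- .find_factor(dataset, x, layers[1])
  fy <- .find_factor(dataset, y, layers[2])
  fz <- .find_factor(dataset, z, layers[3])
  keep <- !is.na(fx$values) & !is.na(fy$values) & !is.na(fz$values)
  n <- sum(keep)
  if (n < 4L)
    .tri_error("triomics_insufficient_overlap",
               sprintf("insufficient overlap: %d complete triples (need >= 4)", n))
  vx <- fx$values[keep]; vy <- fy$values[keep]; vz <- fz$values[keep]
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0 || stats::sd(vz) == 0)
    .tri_error("triomics_degenerate", "degenerate factor: zero variance")
  r_xy <- stats::cor(vx, vy); r_xz <- stats::cor(vx, vz); r_yz <- stats::cor(vy, vz)
  marginals <- c(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz)
  partials <- c(`r_xy.z` = partial_r(r_xy, r_xz, r_yz),
                `r_xz.y` = partial_r(r_xz, r_xy, r_yz),
                `r_yz.x` = partial_r(r_yz, r_xy, r_xz))
  structure(list(
    factors = c(x = x, y = y, z = z),
    layers = c(x = fx$layer, y = fy$layer, z = fz$layer),
    n = as.integer(n), marginals = marginals, partials = partials,
    classification = .classify_triad(marginals, partials,
                                     drop_threshold, retain_threshold),
    drop_threshold = drop_threshold, retain_threshold = retain_threshold),
    class = "triad_report")
}

#' @export
print.triad_report <- function(x, ...) {
  f <- x$factors; l <- x$layers
  cat(sprintf("<triad_report> x = %s [%s], y = %s [%s], z = %s [%s]  (n = %d)\n",
              f["x"], l["x"], f["y"], l["y"], f["z"], l["z"], x$n))
  cat(sprintf("  marginals: r_xy = %.2f, r_xz = %.2f, r_yz = %.2f\n",
              x$marginals["r_xy"], x$marginals["r_xz"], x$marginals["r_yz"]))
  cat(sprintf("  partials : r_xy.z = %.2f, r_xz.y = %.2f, r_yz.x = %.2f\n",
              x$partials["r_xy.z"], x$partials["r_xz.y"], x$partials["r_yz.x"]))
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

.resolve_covariate <- function(metadata, name) {
  key <- tolower(name)
  if (key %in% c("cpeq")) {
    v <- metadata$cpeq
    con <- metadata$diagnosis == "CON"
    v[con & is.na(v)] <- 0  # controls are unmedicated by convention
    if (any(is.na(v) & !con))
      .tri_error("triomics_validation",
                 sprintf("CPeq missing for SCZ sample(s): %s",
                         paste(metadata$sample_id[is.na(v) & !con], collapse = ", ")))
    return(v)
  }
  if (key %in% c("aod", "age")) return(metadata$age)
  if (key %in% names(metadata) && is.numeric(metadata[[key]]))
    return(metadata[[key]])
  .tri_error("triomics_reference", sprintf("unknown covariate '%s'", name))
}

#' Covariate correlation and adjustment analysis
#'
#' For a set of factors (typically a triad), correlates each factor with
#' each clinical covariate — by default antipsychotic dose in
#' chlorpromazine equivalents (`CPeq`, mg/day, 0 for controls) and age at
#' death (`AoD`, years) — and recomputes every factor-pair correlation as a
#' first-order partial controlling each covariate in turn. A factor-pair
#' partial that stays near its marginal shows the covariate does not drive
#' the association; one that collapses flags confounding.
#'
#' @param dataset A `harmonized_dataset` whose metadata carries the
#'   covariates.
#' @param factors Character vector of factor IDs (at least one; partials
#'   need at least two).
#' @param layers Optional layer of each factor (resolved by search when
#'   omitted).
#' @param covariates Covariate names; `"CPeq"` and `"AoD"` (alias `"age"`)
#'   are recognized, plus any numeric metadata column.
#' @return An object of class `"covariate_report"`: `marginals` (data
#'   frame: factor, layer, covariate, n, r) and `partials` (data frame:
#'   factor_a, factor_b, covariate, n, r_marginal, r_partial).
#' @export
covariate_analysis <- function(dataset, factors, layers = NULL,
                               covariates = c("CPeq", "AoD")) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  if (length(factors) < 1L)
    .tri_error("triomics_input", "need at least one factor")
  fs <- lapply(seq_along(factors), function(i)
    .find_factor(dataset, factors[i], layers[i]))
  names(fs) <- factors
  marg <- list(); part <- list()
  for (cv in covariates) {
    w <- .resolve_covariate(dataset$metadata, cv)
    names(w) <- dataset$metadata$sample_id
    for (i in seq_along(factors)) {
      v <- fs[[i]]$values
      keep <- !is.na(v) & !is.na(w)
      if (stats::sd(w[keep]) == 0)
        .tri_error("triomics_degenerate",
                   sprintf("degenerate covariate '%s': constant over the analyzed samples", cv))
      marg[[length(marg) + 1L]] <- data.frame(
        factor = factors[i], layer = fs[[i]]$layer, covariate = cv,
        n = sum(keep), r = stats::cor(v[keep], w[keep]),
        stringsAsFactors = FALSE)
    }
    if (length(factors) >= 2L) {
      cmb <- utils::combn(seq_along(factors), 2L)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1L, k]; j <- cmb[2L, k]
        vi <- fs[[i]]$values; vj <- fs[[j]]$values
        keep <- !is.na(vi) & !is.na(vj) & !is.na(w)
        if (sum(keep) < 4L) next
        if (stats::sd(w[keep]) == 0)
          .tri_error("triomics_degenerate",
                     sprintf("degenerate covariate '%s': constant over the analyzed samples", cv))
        r_ij <- stats::cor(vi[keep], vj[keep])
        r_iw <- stats::cor(vi[keep], w[keep])
        r_jw <- stats::cor(vj[keep], w[keep])
        part[[length(part) + 1L]] <- data.frame(
          factor_a = factors[i], factor_b = factors[j], covariate = cv,
          n = sum(keep), r_marginal = r_ij,
          r_partial = partial_r(r_ij, r_iw, r_jw), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    marginals = do.call(rbind, marg),
    partials = if (length(part)) do.call(rbind, part) else
      data.frame(factor_a = character(), factor_b = character(),
                 covariate = character(), n = integer(),
                 r_marginal = numeric(), r_partial = numeric())),
    class = "covariate_report")
}

#' @export
print.covariate_report <- function(x, ...) {
  cat("<covariate_report>\n  factor-covariate correlations:\n")
  m <- x$marginals
  for (i in seq_len(nrow(m)))
    cat(sprintf("    %s ~ %s: r = %.2f (n = %d)\n",
                m$factor[i], m$covariate[i], m$r[i], m$n[i]))
  p <- x$partials
  if (nrow(p) > 0L) {
    cat("  factor-pair partials controlling each covariate:\n")
    for (i in seq_len(nrow(p)))
      cat(sprintf("    %s ~ %s | %s: r = %.2f -> %.2f (n = %d)\n",
                  p$factor_a[i], p$factor_b[i], p$covariate[i],
                  p$r_marginal[i], p$r_partial[i], p$n[i]))
  }
  invisible(x)
}
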