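test_that("find_triads matches brute-force triangle enumeration", {
  for (seed in c(21, 22, 23, 24)) {
    ds <- make_dataset(seed = seed, n = 10,
                       sizes = c(la = 3, lb = 3, lc = 3))
    screens <- list(cross_layer_screen(ds, "la", "lb", alpha = 0.4),
                    cross_layer_screen(ds, "la", "lc", alpha = 0.4),
                    cross_layer_screen(ds, "lb", "lc", alpha = 0.4))
    sig <- function(s, a, b) {
      r <- s$results
      any(r$significant & r$factor_a == a & r$factor_b == b)
    }
    expected <- 0L
    for (f1 in rownames(ds$layers$la$values))
      for (f2 in rownames(ds$layers$lb$values))
        for (f3 in rownames(ds$layers$lc$values))
          if (sig(screens[[1]], f1, f2) && sig(screens[[2]], f1, f3) &&
              sig(screens[[3]], f2, f3))
            expected <- expected + 1L
    got <- find_triads(screens)
    expect_equal(nrow(got), expected)
    for (i in seq_len(nrow(got))) {
      expect_true(sig(screens[[1]], got$x[i], got$y[i]))
      expect_true(sig(screens[[2]], got$x[i], got$z[i]))
      expect_true(sig(screens[[3]], got$y[i], got$z[i]))
    }
  }
})

test_that("find_triads validates its screen collection and handles empty flags", {
  ds <- make_dataset(seed = 31)
  s1 <- cross_layer_screen(ds, "lipidomics", "transcriptomics", alpha = 1e-6)
  s2 <- cross_layer_screen(ds, "lipidomics", "proteomics", alpha = 1e-6)
  s3 <- cross_layer_screen(ds, "transcriptomics", "proteomics", alpha = 1e-6)
  expect_equal(nrow(find_triads(list(s1, s2, s3))), 0L)
  expect_error(find_triads(list(s1, s2)), class = "triomics_input")
  expect_error(find_triads(list(s1, s1, s3)), class = "triomics_input")
})

test_that("mediation_profile recovers planted mediation and direct structures", {
  coh <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                        structure = "mediated", seed = 101))
  ds <- harmonize(coh$layers, coh$metadata)
  tp <- coh$truth$planted
  pr <- mediation_profile(ds, tp$x$factor, tp$y$factor, tp$z$factor)
  expect_gt(abs(pr$marginals["r_xy"]), 0.8)
  expect_lt(abs(pr$partials["r_xy.z"]), 0.1)
  expect_gte(abs(pr$partials["r_xz.y"]), 0.5)
  expect_identical(pr$classification, "mediated-by-z")

  dcoh <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                         structure = "direct", seed = 102))
  dds <- harmonize(dcoh$layers, dcoh$metadata)
  dtp <- dcoh$truth$planted
  dpr <- mediation_profile(dds, dtp$x$factor, dtp$y$factor, dtp$z$factor)
  expect_equal(dpr$partials[["r_xy.z"]], dpr$marginals[["r_xy"]],
               tolerance = 0.1)
  expect_identical(dpr$classification, "direct")
})

test_that("mediation_profile partials equal the residual oracle on the shared subset", {
  ds <- make_dataset(seed = 55, n = 12,
                     sizes = c(la = 2, lb = 2, lc = 2))
  ds$layers$la$values["la_01", c("S01", "C02")] <- NA
  pr <- mediation_profile(ds, "la_01", "lb_01", "lc_01")
  keep <- ds$common_samples[!is.na(ds$layers$la$values["la_01", ])]
  x <- ds$layers$la$values["la_01", keep]
  y <- ds$layers$lb$values["lb_01", keep]
  z <- ds$layers$lc$values["lc_01", keep]
  expect_equal(pr$n, length(keep))
  expect_equal(pr$partials[["r_xy.z"]], partial_r_oracle(x, y, z),
               tolerance = 1e-9)
  expect_equal(pr$partials[["r_xz.y"]], partial_r_oracle(x, z, y),
               tolerance = 1e-9)
  expect_equal(pr$partials[["r_yz.x"]], partial_r_oracle(y, z, x),
               tolerance = 1e-9)
})

test_that("triad classification tracks factor relabeling", {
  coh <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                        structure = "mediated", seed = 103))
  ds <- harmonize(coh$layers, coh$metadata)
  tp <- coh$truth$planted
  f <- c(tp$x$factor, tp$y$factor, tp$z$factor)
  expect_identical(mediation_profile(ds, f[1], f[2], f[3])$classification,
                   "mediated-by-z")
  expect_identical(mediation_profile(ds, f[3], f[2], f[1])$classification,
                   "mediated-by-x")
  expect_identical(mediation_profile(ds, f[1], f[3], f[2])$classification,
                   "mediated-by-y")
})

test_that("mediation_profile rejects collinear and insufficient input", {
  ds <- make_dataset(seed = 60, sizes = c(la = 2, lb = 2, lc = 2))
  ds$layers$lc$values["lc_01", ] <- ds$layers$la$values["la_01", ]  # duplicate
  expect_error(mediation_profile(ds, "la_01", "lb_01", "lc_01"),
               class = "triomics_collinear")

  ds2 <- make_dataset(seed = 61, sizes = c(la = 1, lb = 1, lc = 1))
  ds2$layers$la$values["la_01", c("S01", "S02", "S03")] <- NA
  expect_error(mediation_profile(ds2, "la_01", "lb_01", "lc_01"),
               class = "triomics_insufficient_overlap")
})

test_that("covariate analysis separates confounding from independence", {
  # confounded: x and y driven by CPeq; controlling it collapses the link
  coh <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                        structure = "confounded", seed = 104))
  ds <- harmonize(coh$layers, coh$metadata)
  tp <- coh$truth$planted
  cv <- covariate_analysis(ds, c(tp$x$factor, tp$y$factor),
                           covariates = "CPeq")
  pair <- cv$partials[1, ]
  expect_gt(abs(pair$r_marginal), 0.5)
  expect_lt(abs(pair$r_partial), 0.15)

  # independent covariate: partial stays near the marginal
  coh2 <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                         structure = "direct", seed = 105))
  ds2 <- harmonize(coh2$layers, coh2$metadata)
  tp2 <- coh2$truth$planted
  cv2 <- covariate_analysis(ds2, c(tp2$x$factor, tp2$y$factor),
                            covariates = "AoD")
  pair2 <- cv2$partials[1, ]
  expect_equal(pair2$r_partial, pair2$r_marginal, tolerance = 0.1)
})

test_that("covariate resolution applies the CPeq conventions", {
  ds <- make_dataset(seed = 70)
  ds$metadata$cpeq[ds$metadata$diagnosis == "CON"] <- NA  # imputed as 0
  cv <- covariate_analysis(ds, "lipi_01", covariates = "CPeq")
  expect_equal(cv$marginals$n, 6L)

  ds$metadata$cpeq[1] <- NA  # an SCZ subject without a recorded dose
  expect_error(covariate_analysis(ds, "lipi_01", covariates = "CPeq"),
               "CPeq missing for SCZ", class = "triomics_validation")

  ds2 <- make_dataset(seed = 71)
  ds2$metadata$cpeq <- 0
  expect_error(covariate_analysis(ds2, "lipi_01", covariates = "CPeq"),
               class = "triomics_degenerate")
  expect_error(covariate_analysis(ds2, "lipi_01", covariates = "bogus"),
               class = "triomics_reference")
})
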