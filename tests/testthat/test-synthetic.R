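test_that("cohort generation is seed-deterministic down to the written bytes", {
  spec <- synthetic_spec(seed = 99, missing_pattern = list(lipi_02 = c("S03", "C03")),
                         outlier = list(factor = "tran_02", sample = "S01",
                                        magnitude = 20))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(spec), d1)
  write_cohort(generate_cohort(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("adding a layer does not perturb existing layers", {
  base <- generate_cohort(synthetic_spec(seed = 5))
  wider <- generate_cohort(synthetic_spec(
    seed = 5, layer_sizes = c(lipidomics = 2, transcriptomics = 7,
                              proteomics = 17, metabolomics = 5)))
  expect_equal(wider$layers$lipidomics$values, base$layers$lipidomics$values)
  expect_equal(wider$layers$proteomics$values, base$layers$proteomics$values)
})

test_that("planted loadings are recovered as population correlations", {
  coh <- generate_cohort(synthetic_spec(n_scz = 500, n_con = 500,
                                        structure = "mediated", seed = 7))
  tp <- coh$truth$planted
  x <- coh$layers[[tp$x$layer]]$values[tp$x$factor, ]
  y <- coh$layers[[tp$y$layer]]$values[tp$y$factor, ]
  z <- coh$layers[[tp$z$layer]]$values[tp$z$factor, ]
  expect_equal(cor(x, z), 0.95, tolerance = 0.03)
  expect_equal(cor(y, z), 0.95, tolerance = 0.03)
  expect_equal(cor(x, y), 0.95^2, tolerance = 0.05)
})

test_that("null cohorts produce null cross-layer correlations", {
  # pool pairs over seeds at the design size n = 6
  rs <- numeric(0)
  for (s in 1:25) {
    coh <- generate_cohort(synthetic_spec(structure = "null",
                                          layer_sizes = c(a = 20, b = 20),
                                          seed = 500 + s))
    ds <- harmonize(coh$layers, coh$metadata)
    sc <- cross_layer_screen(ds, "a", "b", alpha = 0.01)
    rs <- c(rs, sc$results$r)
  }
  expect_equal(mean(rs), 0, tolerance = 0.03)
  expect_lt(abs(mean(abs(rs) >= 0.91719) - 0.01), 0.005)
})

test_that("the truth record captures planted structure and injected outliers", {
  spec <- synthetic_spec(seed = 3, outlier = list(factor = "prot_03",
                                                  sample = "C02", magnitude = 20))
  coh <- generate_cohort(spec)
  expect_identical(coh$truth$structure, "mediated")
  expect_identical(coh$truth$planted$x$layer, "lipidomics")
  expect_identical(coh$truth$planted$z$factor,
                   rownames(coh$layers$proteomics$values)[1])
  o <- coh$truth$outliers[[1]]
  expect_identical(o$factor, "prot_03")
  expect_identical(o$sample, "C02")
  # original value retained; cell moved to mean + 20 sd of the others
  v <- coh$layers$proteomics$values["prot_03", ]
  others <- v[names(v) != "C02"]
  expect_equal(v[["C02"]], mean(others) + 20 * sd(others), tolerance = 1e-12)
  expect_false(identical(o$original_value, v[["C02"]]))

  # truth file round-trips through yaml
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  tr <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(tr$outliers[[1]]$original_value, o$original_value,
               tolerance = 1e-6)
  expect_identical(tr$planted$x$factor, coh$truth$planted$x$factor)
})

test_that("inject_outlier flags under Dixon and validates its target", {
  coh <- generate_cohort(synthetic_spec(seed = 12))
  coh20 <- inject_outlier(coh, "tran_03", "C01", 20)
  d <- dixon_q(coh20$layers$transcriptomics$values["tran_03", ], 0.99)
  expect_true(d$is_outlier)
  expect_identical(d$outlier_sample, "C01")

  # magnitude 0 parks the cell at the mean of the others: not extreme
  coh0 <- inject_outlier(coh, "tran_03", "C01", 0)
  v <- coh0$layers$transcriptomics$values["tran_03", ]
  expect_equal(v[["C01"]], mean(v[names(v) != "C01"]), tolerance = 1e-12)
  expect_false(dixon_q(v, 0.99)$is_outlier)

  expect_error(inject_outlier(coh, "nope", "C01", 5), class = "triomics_reference")
  expect_error(inject_outlier(coh, "tran_03", "Z99", 5), class = "triomics_reference")
  cohNA <- generate_cohort(synthetic_spec(seed = 12,
                                          missing_pattern = list(tran_03 = "C01")))
  expect_error(inject_outlier(cohNA, "tran_03", "C01", 5),
               class = "triomics_reference")
})

test_that("written cohorts round-trip through the readers", {
  spec <- synthetic_spec(seed = 44, missing_pattern = list(lipi_02 = c("S01", "C02")))
  coh <- generate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  lip <- read_omics_layer(file.path(d, "lipidomics.tsv"), "lipidomics")
  expect_equal(lip$values, coh$layers$lipidomics$values, tolerance = 1e-12)
  md <- read_sample_metadata(file.path(d, "metadata.tsv"))
  expect_equal(md$sample_id, coh$metadata$sample_id)
  expect_equal(md$cpeq, coh$metadata$cpeq)

  ds <- harmonize(list(lip, read_omics_layer(file.path(d, "transcriptomics.tsv"),
                                             "transcriptomics")), md)
  expect_equal(ds$availability$lipidomics[["lipi_02"]], 4)
})

test_that("spec validation rejects inconsistent requests", {
  expect_error(synthetic_spec(n_scz = 1, n_con = 1), class = "triomics_input")
  expect_error(synthetic_spec(loading_a = 1), class = "triomics_input")
  expect_error(synthetic_spec(structure = "mediated",
                              layer_sizes = c(a = 2, b = 2)),
               class = "triomics_input")
  expect_error(generate_cohort(synthetic_spec(
    seed = 1, missing_pattern = list(ghost = "S01"))),
    class = "triomics_validation")
  expect_error(generate_cohort(synthetic_spec(
    seed = 1, outlier = list(factor = "ghost", sample = "S01", magnitude = 5))),
    class = "triomics_reference")
})
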