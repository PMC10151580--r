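Package: triomics
Title: Cross-Layer Correlation Screening and Mediation Triangulation for
    Small Multi-Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trans-omics correlation analysis for small case-control
    cohorts measured on several omics layers (e.g. lipidomics,
    transcriptomics, proteomics) over the same samples. Implements exact
    small-sample Pearson correlation significance via inversion of the
    Student t distribution (critical |r| per degrees of freedom), Dixon's
    Q outlier screening with tabulated two-tailed critical values,
    all-pairs cross-layer correlation screening with pairwise-complete
    observations, first-order partial-correlation mediation triangulation
    among mutually correlated cross-layer triads, and covariate-adjusted
    partial correlations (antipsychotic dose, age at death). A synthetic
    cohort generator with planted mediation, direct-edge, confounded and
    null structures, configurable missingness and injected outliers makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
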