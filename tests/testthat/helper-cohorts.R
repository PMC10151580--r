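# shared fixture builders; everything is generated in code at test time

# a tiny deterministic 3-layer dataset with given per-layer factor counts
make_dataset <- function(seed = 1, n = 6, sizes = c(lipidomics = 2,
                                                    transcriptomics = 3,
                                                    proteomics = 3)) {
  set.seed(seed)
  ids <- c(sprintf("S%02d", seq_len(ceiling(n / 2))),
           sprintf("C%02d", seq_len(floor(n / 2))))
  layers <- lapply(names(sizes), function(ln) {
    m <- matrix(rnorm(sizes[[ln]] * n), nrow = sizes[[ln]],
                dimnames = list(sprintf("%s_%02d", substr(ln, 1, 4),
                                        seq_len(sizes[[ln]])), ids))
    omics_layer(m, name = ln)
  })
  md <- data.frame(sample_id = ids,
                   diagnosis = rep(c("SCZ", "CON"),
                                   c(ceiling(n / 2), floor(n / 2))),
                   age = seq(60, by = 2, length.out = n),
                   sex = rep(c("Male", "Female"), length.out = n),
                   pmi = seq(5, by = 3, length.out = n),
                   doi = rep(c(30, 0), c(ceiling(n / 2), floor(n / 2))),
                   cpeq = rep(c(400, 0), c(ceiling(n / 2), floor(n / 2))) +
                     seq(0, by = 10, length.out = n) *
                     rep(c(1, 0), c(ceiling(n / 2), floor(n / 2))),
                   cause_of_death = "synthetic",
                   stringsAsFactors = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  harmonize(layers, md)
}

# the shipped six-subject metadata fixture
fixture_metadata <- function() {
  read_sample_metadata(system.file("extdata", "subject_metadata.tsv",
                                   package = "triomics"))
}

# residual-regression oracle for the first-order partial correlation
partial_r_oracle <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  cor(rx, ry)
}
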