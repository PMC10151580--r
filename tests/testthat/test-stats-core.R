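test_that("pearson_r reproduces hand-computed coefficients and metadata", {
  x <- 1:6
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)

  # brute-force product-moment sums: cov sum 14.5, each variance sum 17.5
  res <- pearson_r(x, c(2, 1, 4, 3, 6, 5), alpha = 0.01)
  expect_equal(res$r, 14.5 / 17.5, tolerance = 1e-12)
  expect_equal(res$n, 6L)
  expect_equal(res$df, 4L)
  expect_equal(res$t, t_from_r(res$r, res$n))
  expect_identical(res$significant, abs(res$r) >= res$r_crit)
})

test_that("pearson_r uses pairwise-complete observations and rejects degenerate input", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, NA, 5, 4, 7, 9)
  keep <- c(1, 3, 4, 6)
  res <- pearson_r(x, y)
  expect_equal(res$n, 4L)
  expect_equal(res$r, cor(x[keep], y[keep]))

  expect_error(pearson_r(c(1, NA, NA, 4, NA), c(1, 2, 3, NA, 5)),
               class = "triomics_insufficient_overlap")
  expect_error(pearson_r(rep(2, 5), 1:5), class = "triomics_degenerate")
})

test_that("t_from_r matches the analytic formula and signals edge cases", {
  expect_equal(t_from_r(0.91719, 6), 4.604, tolerance = 0.001)
  expect_equal(t_from_r(0, 10), 0)
  expect_equal(t_from_r(0.5, 6), 1 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(t_from_r(-0.5, 6), t_from_r(0.5, 6))  # two-sided statistic
  expect_error(t_from_r(1, 6), class = "triomics_infinite_t")
  expect_error(t_from_r(1.2, 6), class = "triomics_input")
  expect_error(t_from_r(0.5, 2), class = "triomics_input")
})

test_that("critical thresholds invert the t quantile exactly", {
  th4 <- critical_thresholds(0.01, 4)
  expect_equal(th4$t_crit, 4.604, tolerance = 5e-4)
  expect_equal(th4$r_crit, 0.91719, tolerance = 1e-4)

  expect_equal(critical_thresholds(0.01, 2)$r_crit, 0.99005, tolerance = 1e-4)
  expect_equal(critical_thresholds(0.05, 4)$r_crit, 0.8114, tolerance = 1e-4)

  # r_crit strictly decreasing in df, increasing as alpha shrinks
  rc <- sapply(1:30, function(d) critical_thresholds(0.01, d)$r_crit)
  expect_true(all(diff(rc) < 0))
  expect_true(critical_thresholds(0.001, 10)$r_crit >
                critical_thresholds(0.01, 10)$r_crit)

  expect_error(critical_thresholds(0, 4), class = "triomics_input")
  expect_error(critical_thresholds(0.05, 0), class = "triomics_input")
})

test_that("t_from_r and critical_thresholds round-trip across df and alpha", {
  for (alpha in c(0.1, 0.05, 0.01)) {
    for (df in 1:30) {
      th <- critical_thresholds(alpha, df)
      expect_equal(t_from_r(th$r_crit, df + 2), th$t_crit, tolerance = 1e-6)
    }
  }
})

test_that("partial_r evaluates the first-order formula and its symmetries", {
  expect_equal(partial_r(0.5, 0, 0), 0.5)
  expect_equal(partial_r(0.72, 0.9, 0.8), 0)  # r_xy = r_xz * r_yz
  expect_equal(partial_r(0.96, -0.98, -0.97), 0.1943, tolerance = 5e-4)
  expect_error(partial_r(0.5, 1, 0.3), class = "triomics_collinear")
  expect_error(partial_r(1.5, 0.2, 0.3), class = "triomics_input")

  set.seed(11)
  for (i in 1:50) {
    r <- cor(matrix(rnorm(30), ncol = 3))  # a consistent correlation triple
    expect_equal(partial_r(r[1, 2], r[1, 3], r[2, 3]),
                 partial_r(r[2, 1], r[2, 3], r[1, 3]))  # x/y exchange
    expect_lte(abs(partial_r(r[1, 2], r[1, 3], r[2, 3])), 1)
  }
})

test_that("partial_r agrees with the least-squares residual oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    x <- rnorm(n); z <- rnorm(n)
    y <- 0.5 * z + rnorm(n)
    r <- partial_r(cor(x, y), cor(x, z), cor(y, z))
    expect_equal(r, partial_r_oracle(x, y, z), tolerance = 1e-9)
    expect_equal(partial_r_data(x, y, z)$r_partial, r, tolerance = 1e-12)
  }
})

test_that("pearson_r and dixon_q are affine invariant", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(8)
  base_r <- pearson_r(x, y)$r
  expect_equal(pearson_r(3.2 * x + 1, y)$r, base_r, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x + 4, y)$r, -base_r, tolerance = 1e-12)

  d0 <- dixon_q(x)
  d1 <- dixon_q(5 * x - 2)
  expect_equal(d1$q_low, d0$q_low, tolerance = 1e-12)
  expect_equal(d1$q_high, d0$q_high, tolerance = 1e-12)
  expect_identical(d1$is_outlier, d0$is_outlier)
})

test_that("dixon_q computes the r10 statistic against tabulated critical values", {
  # six post-mortem intervals (hours); the 42 h subject is extreme but the
  # gap/range ratio 25/38 stays below the 99% critical value 0.740
  pmi <- c(S01 = 15.0, S02 = 16.5, S03 = 17.0, C01 = 8.0, C02 = 4.0, C03 = 42.0)
  d <- dixon_q(pmi, confidence = 0.99)
  expect_equal(d$q_high, 25 / 38, tolerance = 1e-12)
  expect_equal(d$q_low, 4 / 38, tolerance = 1e-12)
  expect_equal(d$q_crit, 0.740)
  expect_false(d$is_outlier)
  expect_identical(d$outlier_sample, "")

  d2 <- dixon_q(c(a = 1, b = 2, c = 3, d = 4, e = 100), confidence = 0.99)
  expect_equal(d2$q_high, 96 / 99, tolerance = 1e-12)
  expect_equal(d2$q_crit, 0.821)
  expect_true(d2$is_outlier)
  expect_identical(d2$outlier_sample, "e")

  expect_error(dixon_q(rep(3, 6)), class = "triomics_degenerate")
  expect_error(dixon_q(c(1, 2)), class = "triomics_input")
  expect_error(dixon_q(rnorm(31)), class = "triomics_input")
  expect_error(dixon_q(1:6, confidence = 0.98), class = "triomics_input")

  # invariant: flag fires exactly when max(q_low, q_high) reaches the table
  set.seed(9)
  for (i in 1:50) {
    v <- rnorm(sample(3:30, 1))
    d <- dixon_q(v, confidence = 0.95)
    expect_identical(d$is_outlier, max(d$q_low, d$q_high) >= d$q_crit)
    expect_true(d$q_low >= 0 && d$q_low <= 1 && d$q_high >= 0 && d$q_high <= 1)
  }
})
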