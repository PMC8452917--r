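test_that("Pearson correlation matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 1, 3))$r, 0.5, tolerance = 1e-12)
  expect_error(pearson_r(x, c(1, 1, 1)),
               class = "coroflow_degenerate_input_error")
  expect_error(pearson_r(c(1, 2), c(1, 2)),
               class = "coroflow_insufficient_data_error")
})

test_that("Bland-Altman bias and limits follow the definition", {
  x <- c(0.8, 0.85, 0.9)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  y <- x - c(0.01, 0.02, 0.03)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0.02, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.01, tolerance = 1e-12)
  expect_equal(ba$loa_low, 0.0004, tolerance = 1e-10)
  expect_equal(ba$loa_high, 0.0396, tolerance = 1e-10)
  # antisymmetry: swapping methods negates the bias and mirrors the limits
  ba_sw <- bland_altman(y, x)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(c(ba_sw$loa_low, ba_sw$loa_high), -c(ba$loa_high, ba$loa_low))
  # reporting convention
  expect_output(print(ba), "mean difference 0.020, 95% limits of agreement",
                fixed = TRUE)
  expect_error(bland_altman(1, numeric(0)),
               class = "coroflow_insufficient_data_error")
})

test_that("diagnostic metrics reproduce a worked 2x2 table", {
  pred <- c(rep(TRUE, 4), FALSE, rep(TRUE, 3), rep(FALSE, 22))
  truth <- c(rep(TRUE, 5), rep(FALSE, 25))
  dm <- diagnostic_metrics(pred, truth)
  expect_identical(c(dm$tp, dm$fp, dm$fn, dm$tn), c(4L, 3L, 1L, 22L))
  expect_equal(dm$sensitivity, 80)
  expect_equal(dm$specificity, 88)
  expect_equal(dm$ppv, 400 / 7, tolerance = 1e-12)
  expect_equal(dm$npv, 2200 / 23, tolerance = 1e-12)
  expect_equal(dm$accuracy, 2600 / 30, tolerance = 1e-12)
  # identities hold exactly on random tables
  set.seed(42)
  for (i in 1:20) {
    p <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    t <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (sum(t) == 0 || sum(!t) == 0 || sum(p) == 0 || sum(!p) == 0) next
    m <- diagnostic_metrics(p, t)
    expect_equal(m$sensitivity * (m$tp + m$fn), 100 * m$tp)
    expect_equal(m$specificity * (m$tn + m$fp), 100 * m$tn)
    expect_equal(m$accuracy * 40, 100 * (m$tp + m$tn))
  }
  all_right <- diagnostic_metrics(truth, truth)
  expect_equal(c(all_right$sensitivity, all_right$specificity,
                 all_right$accuracy), c(100, 100, 100))
  expect_error(diagnostic_metrics(pred, rep(FALSE, 30)),
               class = "coroflow_undefined_metric_error")
})

test_that("reproducibility indices behave at the degenerate limits", {
  a <- c(0.85, 0.80, 0.90, 0.83, 0.88, 0.79, 0.92, 0.86, 0.81, 0.87)
  perfect <- reproducibility_stats(a, a)
  expect_equal(perfect$icc, 1, tolerance = 1e-9)
  expect_equal(perfect$cov_percent, 0)
  shifted <- reproducibility_stats(a, a + 0.01)
  expect_equal(shifted$bland_altman$bias, -0.01, tolerance = 1e-12)
  expect_equal(shifted$bland_altman$sd_diff, 0, tolerance = 1e-12)
  expect_error(reproducibility_stats(a[1:2], a[1:2]),
               class = "coroflow_insufficient_data_error")
})

test_that("the absolute-agreement single-measure ICC matches an external oracle", {
  # expected value frozen from an independent two-way ANOVA implementation
  a <- c(0.85, 0.80, 0.90, 0.83, 0.88, 0.79, 0.92, 0.86, 0.81, 0.87)
  b <- c(0.86, 0.805, 0.89, 0.84, 0.875, 0.80, 0.915, 0.865, 0.815, 0.875)
  r <- reproducibility_stats(a, b)
  expect_equal(r$icc, 0.983508, tolerance = 1e-6)
  expect_true(r$icc_ci[1] < r$icc && r$icc <= 1)
})

test_that("the COV estimate brackets its analytic value for seeded noise", {
  # two independent measurements with noise sd 0.01 around a 0.85 mean:
  # SD of differences is 0.01*sqrt(2), so COV ~ 1.66%
  ab <- with(list(), {
    set.seed(77)
    m <- 0.85 + stats::runif(10, -0.03, 0.03)
    list(a = m + stats::rnorm(10, 0, 0.01), b = m + stats::rnorm(10, 0, 0.01))
  })
  r <- reproducibility_stats(ab$a, ab$b, seed = 5)
  expect_true(r$cov_ci[1] <= 100 * 0.01 * sqrt(2) / 0.85)
  expect_true(r$cov_ci[2] >= 100 * 0.01 * sqrt(2) / 0.85 * 0.5)
  # bootstrap is seed-reproducible
  r2 <- reproducibility_stats(ab$a, ab$b, seed = 5)
  expect_identical(r$cov_ci, r2$cov_ci)
})

test_that("correlation strengthens as the measurement noise shrinks", {
  co <- generate_validation_cohort(
    cohort_spec(n_patients = 12, seed = 31, bias = 0, noise_sd = 0))
  pre <- co$paired[co$paired$phase == "pre", ]
  rs <- vapply(c(0.10, 0.04, 0.01), function(sd_k) {
    noisy <- coroflow:::with_seed(99, pre$ffr_b + stats::rnorm(nrow(pre), 0, sd_k))
    pearson_r(pre$ffr_b, noisy)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})
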