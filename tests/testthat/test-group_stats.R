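test_that("Welch t-test matches the textbook closed form", {
  a <- c(4.1, 5.2, 3.9, 4.8, 5.0)
  b <- c(6.3, 5.9, 7.1, 6.8, 6.0)
  res <- welch_ttest(a, b)
  va <- var(a) / 5; vb <- var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
})

test_that("degenerate Welch inputs behave as specified", {
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  res <- welch_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(welch_ttest(1, c(1, 2)), ">= 2")
})

test_that("Welch test calibration and power behave nominally", {
  set.seed(61)
  # type-I at alpha = .05 under the null
  rej <- mean(replicate(2000, welch_ttest(rnorm(15), rnorm(15))$p < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  # power against a 2-sigma shift with n = 26 vs 32
  pow <- mean(replicate(500, welch_ttest(rnorm(26), rnorm(32, 2))$p < 0.05))
  expect_gt(pow, 0.99)
})

test_that("Holm correction reproduces the step-down hand example", {
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2), 0.2)
  expect_equal(holm_correct(c(1, 1, 1)), c(1, 1, 1))
  set.seed(62)
  p <- runif(8)
  h <- holm_correct(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(1, length(p) * p)))
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("robust regression recovers exact lines and rejects constants", {
  x <- 1:10
  res <- robust_regression(x, 2 * x + 1)
  expect_equal(res$slope, 2, tolerance = 1e-9)
  expect_equal(res$intercept, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_error(robust_regression(rep(3, 5), rnorm(5)), "constant")
  expect_error(robust_regression(1:2, 1:2), ">= 3")
})

test_that("robust regression resists a gross outlier", {
  set.seed(63)
  x <- seq(0, 1, length.out = 20)
  y <- 3 * x + rnorm(20, sd = 0.05)
  y[20] <- -40
  rob <- robust_regression(x, y)
  ols <- coef(lm(y ~ x))[2]
  expect_lt(abs(rob$slope - 3), 0.3)
  expect_gt(abs(ols - 3), 5)
})

test_that("family-wise error of the Holm-corrected band battery stays near nominal", {
  # scaled-down null: both groups drawn from one distribution, the full
  # 3-band Welch + Holm path per metric family
  set.seed(64)
  n_sim <- 500
  fwer <- mean(replicate(n_sim, {
    tbl <- data.frame(
      band = rep(c("delta", "theta", "alpha"), each = 20),
      value = rnorm(60),
      is_patient = rep(rep(c(FALSE, TRUE), each = 10), 3))
    out <- modspan:::band_family_tests(tbl, "value")
    any(out$p_corrected < 0.05)
  }))
  expect_lte(fwer, 0.07)
})

test_that("the robust slope CI covers a true null slope at nominal rate", {
  set.seed(65)
  cover <- mean(replicate(200, {
    x <- runif(15, 0.05, 0.7)
    y <- 6 + 0 * x + rnorm(15)
    r <- robust_regression(x, y)
    r$slope_lo <= 0 && r$slope_hi >= 0
  }))
  expect_gte(cover, 0.9)
})

test_that("single-group cohorts skip group tests with a notice", {
  skip_if_not(exists("cohort_report"))
  res <- structure(list(
    subjects = data.frame(subject_id = c("C1", "C2", "C3"),
                          group = "control", crs_r = NA_integer_,
                          imagery = NA),
    band_power = data.frame(subject_id = rep(c("C1", "C2", "C3"), each = 2),
                            band = rep(c("delta", "alpha"), 3),
                            contribution = runif(6)),
    band_variability = data.frame(subject_id = rep(c("C1", "C2", "C3"), each = 2),
                                  band = rep(c("delta", "alpha"), 3),
                                  variability = runif(6)),
    graph_metrics = data.frame(subject_id = rep(c("C1", "C2", "C3"), each = 1),
                               band = "alpha", mean_dwpli = runif(3),
                               clustering = runif(3), path_length = runif(3),
                               efficiency = runif(3), modularity = runif(3),
                               participation_sd = runif(3),
                               modular_span = runif(3)),
    nmi = NULL, retained_epochs = c(C1 = 60, C2 = 60, C3 = 60),
    montage = NULL, seed = 1), class = "cohort_results")
  rep_ <- cohort_report(res)
  expect_null(rep_$graph_tests)
  expect_match(rep_$notes, "single-group", all = FALSE)
})
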