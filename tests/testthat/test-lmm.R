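test_that("signed square root is odd, monotone and round-trips", {
  expect_equal(signed_sqrt(9), 3)
  expect_equal(signed_sqrt(0), 0)
  expect_equal(signed_sqrt(-4), -2)
  expect_equal(signed_sqrt(-4, literal = TRUE), 2)   # the non-preserving form
  x <- seq(-5, 5, by = 0.1)
  y <- signed_sqrt(x)
  expect_equal(y, -signed_sqrt(-x))                  # odd
  expect_true(all(diff(y) > 0))                      # strictly increasing
  expect_equal(sign(y) * y^2, x, tolerance = 1e-12)  # inverse round-trip
})

test_that("balanced one-level REML equals the closed-form ANOVA solution", {
  for (seed in c(3, 11)) {
    d <- simulate_dbv_records(n_rats = 8, n_stim = 5, delta = 1,
                              sigma_rat = 0.7, sigma_res = 1, seed = seed)
    fit <- fit_lmm(d, "one_level")
    a <- 8; n <- 5
    ybar_i <- tapply(d$y, d$rat, mean)
    gm <- mean(d$y)
    msb <- n * sum((ybar_i - gm)^2) / (a - 1)
    msw <- sum((d$y - ybar_i[d$rat])^2) / (a * (n - 1))
    expect_equal(fit$delta_hat, gm, tolerance = 1e-6)
    expect_equal(unname(fit$sigma2["rat"]), max(0, (msb - msw) / n),
                 tolerance = 1e-6)
    expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
  }
})

test_that("degenerate groupings are flagged, not silently altered", {
  # one observation per rat: rat and residual variances confounded
  d1 <- simulate_dbv_records(n_rats = 10, n_stim = 1, delta = 0.5,
                             sigma_rat = 0, sigma_res = 1, seed = 4)
  f1 <- fit_lmm(d1, "one_level")
  expect_true(f1$flags$collapsed)
  expect_true(is.na(f1$sigma2["rat"]))
  # F equals the squared one-sample t statistic, df n - 1
  tt <- t.test(d1$y)
  ft <- test_fixed_effect(f1)
  expect_equal(ft$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ft$df2, 9)
  expect_equal(ft$p.value, tt$p.value, tolerance = 1e-10)

  # two-level with one acquisition per rat: acquisition confounded with rat
  d2 <- simulate_dbv_records(n_rats = 6, n_acq = 1, n_stim = 4, delta = 1,
                             sigma_rat = 0.5, sigma_res = 1, seed = 5)
  expect_warning(f2 <- fit_lmm(d2, "two_level"), "confound")
  expect_true(f2$flags$acq_confounded)
  expect_equal(f2$form, "one_level")

  expect_error(fit_lmm(simulate_dbv_records(1, n_stim = 5, seed = 1),
                       "one_level"), "rat")
})

test_that("a zero rat effect yields near-zero variance and the sample mean", {
  d <- simulate_dbv_records(n_rats = 12, n_stim = 6, delta = 2,
                            sigma_rat = 0, sigma_res = 1, seed = 7)
  fit <- fit_lmm(d, "one_level")
  expect_equal(fit$delta_hat, mean(d$y), tolerance = 1e-6)
  expect_lt(unname(fit$sigma2["rat"]), 0.05)
})

test_that("delta is translation-equivariant, variances invariant", {
  d <- simulate_dbv_records(n_rats = 6, n_stim = 4, delta = 0.3,
                            sigma_rat = 0.5, sigma_res = 1, seed = 8)
  f0 <- fit_lmm(d, "one_level")
  d$y <- d$y + 3.7
  f1 <- fit_lmm(d, "one_level")
  expect_equal(f1$delta_hat, f0$delta_hat + 3.7, tolerance = 1e-6)
  expect_equal(f1$sigma2, f0$sigma2, tolerance = 1e-5)
})

test_that("parameter recovery over replicates hits the simulated truth", {
  # moderately scaled-down replicate study: the estimator is unbiased for
  # delta and sigma2_rat at the simulated 20 rats x 5 stimulations
  n_rep <- 120
  est <- vapply(seq_len(n_rep), function(r) {
    d <- simulate_dbv_records(n_rats = 20, n_stim = 5, delta = 1,
                              sigma_rat = 0.5, sigma_res = 1, seed = 1000 + r)
    fit <- fit_lmm(d, "one_level")
    c(fit$delta_hat, fit$sigma2["rat"])
  }, numeric(2))
  expect_equal(mean(est[1, ]), 1, tolerance = 0.05)
  expect_equal(mean(est[2, ]), 0.25, tolerance = 0.05)
})

test_that("fixed-effect F test is calibrated under the null and powered", {
  n_rep <- 400
  # an occasional replicate triggers a benign lme4 convergence warning
  pvals <- suppressWarnings(vapply(seq_len(n_rep), function(r) {
    d <- simulate_dbv_records(n_rats = 10, n_stim = 3, delta = 0,
                              sigma_rat = 0.5, sigma_res = 1, seed = 2000 + r)
    test_fixed_effect(fit_lmm(d, "one_level"))$p.value
  }, numeric(1)))
  t1 <- mean(pvals < 0.05)
  expect_gt(t1, 0.05 - 0.03)
  expect_lt(t1, 0.05 + 0.03)

  strong <- vapply(1:60, function(r) {
    d <- simulate_dbv_records(n_rats = 10, n_stim = 3, delta = 3,
                              sigma_rat = 0.5, sigma_res = 1, seed = 3000 + r)
    test_fixed_effect(fit_lmm(d, "one_level"))$p.value
  }, numeric(1))
  expect_gte(mean(strong < 0.001), 0.95)
})

test_that("random-effect likelihood-ratio test behaves at null and alternative", {
  # identical models: LR = 0, p = 1
  d <- simulate_dbv_records(n_rats = 8, n_acq = 2, n_stim = 3, delta = 1,
                            sigma_rat = 0.6, sigma_acq = 0.4, sigma_res = 1,
                            seed = 6)
  full <- fit_lmm(d, "two_level")
  expect_equal(test_random_effect(full, full0 <- full)$statistic, 0)
  expect_error(test_random_effect(full,
                                  fit_lmm(simulate_dbv_records(8, 1, 2, seed = 1),
                                          "one_level")), "nested|observations")

  # null sigma_rat: LR stochastically below the chi2_1 reference (conservative)
  n_rep <- 150
  pv <- vapply(seq_len(n_rep), function(r) {
    dn <- simulate_dbv_records(n_rats = 8, n_stim = 4, delta = 1,
                               sigma_rat = 0, sigma_res = 1, seed = 4000 + r)
    f <- fit_lmm(dn, "one_level")
    test_random_effect(f, fit_lmm(dn, "none"))$p.value
  }, numeric(1))
  expect_lte(mean(pv < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))

  # large sigma_rat: overwhelming rejection
  pv2 <- vapply(1:40, function(r) {
    da <- simulate_dbv_records(n_rats = 10, n_stim = 5, delta = 1,
                               sigma_rat = 2, sigma_res = 1, seed = 5000 + r)
    f <- fit_lmm(da, "one_level")
    test_random_effect(f, fit_lmm(da, "none"))$p.value
  }, numeric(1))
  expect_gte(mean(pv2 < 0.05), 0.95)
})

test_that("residual normality check is calibrated and powered", {
  # gaussian residuals: Shapiro p approximately uniform across seeds
  pv <- vapply(1:120, function(r) {
    d <- simulate_dbv_records(n_rats = 10, n_stim = 5, delta = 0,
                              sigma_rat = 0.4, sigma_res = 1, seed = 6000 + r)
    check_residual_normality(fit_lmm(d, "one_level"))$p.value
  }, numeric(1))
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)

  # heavily skewed residuals: rejected in at least 90% of seeds
  pv2 <- vapply(1:40, function(r) {
    d <- simulate_dbv_records(n_rats = 10, n_stim = 5, delta = 0,
                              sigma_rat = 0, sigma_res = 1, seed = 7000 + r)
    d$y <- exp(d$y)
    check_residual_normality(fit_lmm(d, "one_level"))$p.value
  }, numeric(1))
  expect_gte(mean(pv2 < 0.05), 0.9)

  # minimal n = 3 input returns a finite statistic
  d3 <- tibble::tibble(rat = factor(c(1, 2, 3)), y = c(0.2, -0.1, 0.4))
  f3 <- fit_lmm(d3, "one_level")
  expect_true(is.finite(check_residual_normality(f3)$statistic))
})

test_that("tidy and glance return the broom-shaped summaries", {
  d <- simulate_dbv_records(n_rats = 6, n_acq = 2, n_stim = 3, delta = 1,
                            sigma_rat = 0.5, sigma_acq = 0.3, sigma_res = 1,
                            seed = 10)
  fit <- fit_lmm(d, "two_level")
  td <- tidy(fit)
  expect_setequal(td$term, c("delta", "var_rat", "var_acquisition", "var_residual"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 36L)
  expect_true(is.finite(gl$logLik_reml))
})
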