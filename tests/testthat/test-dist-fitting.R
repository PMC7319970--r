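# MLE fitting, AIC selection, R-squared diagnostic and summaries.

test_that("closed-form MLEs are exact on worked examples", {
  f <- fit_mle(c(1, 2, 3), "exponential")
  expect_equal(f$params[["rate"]], 0.5)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)

  f <- fit_mle(c(1, exp(1)), "pareto")
  expect_equal(f$params[["xmin"]], 1)
  expect_equal(f$params[["alpha"]], 2)

  f <- fit_mle(c(2, 4, 6), "normal")
  expect_equal(f$params[["mean"]], 4)
  expect_equal(f$params[["sd"]], popsd(c(2, 4, 6)))

  f <- fit_mle(exp(c(0, 1, 2)), "lognormal")
  expect_equal(f$params[["meanlog"]], 1)
  expect_equal(f$params[["sdlog"]], popsd(c(0, 1, 2)))
})

test_that("analytic log-likelihoods agree with dedensity sums and an external fitter", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    x <- stats::rlnorm(n, stats::rnorm(1), stats::runif(1, 0.3, 1.5))
    fe <- fit_mle(x, "exponential")
    fl <- fit_mle(x, "lognormal")
    expect_equal(fe$loglik, sum(stats::dexp(x, fe$params[["rate"]], log = TRUE)),
                 tolerance = 1e-8)
    expect_equal(fl$loglik,
                 sum(stats::dlnorm(x, fl$params[["meanlog"]], fl$params[["sdlog"]],
                                   log = TRUE)),
                 tolerance = 1e-8)
    # ordering of the two log-likelihoods matches the independent evaluation
    expect_identical(fe$loglik > fl$loglik,
                     sum(stats::dexp(x, 1 / mean(x), log = TRUE)) >
                       sum(stats::dlnorm(x, mean(log(x)), popsd(log(x)), log = TRUE)))
  }
  # cross-check against fitdistrplus MLE (sample-SD vs population-SD differ;
  # compare the exponential, whose MLE is convention-free)
  skip_if_not_installed("fitdistrplus")
  set.seed(22)
  x <- stats::rexp(500, 3)
  ref <- fitdistrplus::fitdist(x, "exp")
  expect_equal(fit_mle(x, "exponential")$params[["rate"]],
               unname(ref$estimate), tolerance = 1e-6)
  expect_equal(fit_mle(x, "exponential")$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("MLEs recover generating parameters on large samples", {
  errs <- mle_recovery_errors(n = 1e5, seed = 5)
  expect_lt(max(errs), 0.02)
})

test_that("zeros are removed for positive-support families and counted", {
  x <- c(0, 0, stats::rlnorm(50, 0, 1))
  f <- fit_mle(x, "lognormal")
  expect_identical(f$n_zero, 2L)
  expect_identical(f$n, 50L)
  full <- fit_mle(x, "exponential")
  expect_identical(full$n, 52L)
  expect_error(fit_mle(c(-1, 1, 2), "pareto"), "negative")
  expect_error(fit_mle(c(1), "exponential"), "insufficient")
})

test_that("AIC selection is deterministic, permutation-invariant and tie-ruled", {
  x <- c(5, 5, 5 + 1e-9)
  s1 <- aic_select(x)
  s2 <- aic_select(x)
  expect_identical(s1$best$family, s2$best$family)
  set.seed(33)
  y <- stats::rlnorm(200, 1, 0.7)
  expect_identical(aic_select(y)$best$family, aic_select(sample(y))$best$family)
  expect_equal(aic_select(y)$best$aic, aic_select(sample(y))$best$aic, tolerance = 1e-9)
  # pareto k flag changes its AIC accounting
  expect_equal(aic_select(y, pareto_k = 1)$fits$pareto$aic,
               aic_select(y, pareto_k = 2)$fits$pareto$aic - 2)
})

test_that("selection accuracy grows with sample size for every family", {
  for (fam in c("exponential", "normal", "lognormal", "pareto")) {
    acc <- vapply(c(200, 1000, 5000), function(n) {
      aic_selection_accuracy(fam, n = n, reps = 40, seed = 210)
    }, 0)
    expect_true(acc[3] >= acc[1], label = fam)
    expect_gte(acc[3], 0.95)
  }
})

test_that("R-squared definition and behaviour", {
  emp <- c(0.5, 0.3, 0.1, 0.05)
  expect_equal(density_r_squared(emp, emp), 1)
  expect_equal(density_r_squared(emp, rep(mean(emp), 4)), 0)
  # good fits on matched data score highly
  set.seed(41)
  r2 <- vapply(1:100, function(k) {
    x <- stats::rlnorm(1e4, 0.2, 0.9)
    fit_r_squared(x, fit_mle(x, "lognormal"))
  }, 0)
  expect_true(all(r2 >= 0.9))
  # undefined with too few occupied bins
  f <- fit_mle(c(1, 1, 1 + 1e-12), "normal")
  expect_true(is.na(fit_r_squared(c(1, 1, 1 + 1e-12), f)))
})

test_that("summaries use the linear-interpolation quantile convention", {
  s <- summarize_sample(1:5)
  expect_equal(s$median, 3)
  s <- summarize_sample(1:10)
  expect_equal(s$p90, 9.1)
  s <- summarize_sample(rep(4.2, 7))
  expect_equal(s$median, 4.2)
  expect_equal(s$p90, 4.2)
  expect_identical(s$n, 7L)
})
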