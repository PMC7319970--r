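# Inferential layer: correlations, mixed models, logistic models,
# KS test and agreement measures.

# synthetic step table with a controllable interval -> acoustic coupling
make_steps <- function(n_per_infant = 500, n_infants = 10, slope = 0,
                       seed = 1, shuffle = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_len(n_infants), function(i) {
    interval <- stats::rlnorm(n_per_infant, 1, 1)
    s2d <- slope * interval + stats::rlnorm(n_per_infant, -0.5, 0.6) +
      stats::rnorm(1, 0, 0.2) # infant-level intercept
    data.frame(infant_id = sprintf("inf%02d", i),
               age_days = sample(c(92, 184, 276, 548), 1),
               recording = sprintf("inf%02d_r", i),
               speaker_type = "infant", subrecording_id = 0L,
               interval_s = interval,
               d_pitch = s2d / sqrt(2), d_amp = s2d / sqrt(2), s_2d = s2d,
               split_class = sample(c("WR", "WOR"), n_per_infant, TRUE),
               in_split_analysis = TRUE, stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, rows)
  if (shuffle) st$interval_s <- sample(st$interval_s)
  st
}

test_that("pearson correlation behaves at its extremes and contracts", {
  st <- make_steps(50, 1)
  st$s_2d <- 2 * st$interval_s
  res <- correlate_step_interval(st)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # independently permuted -> near-zero correlation
  big <- make_steps(10000, 1, seed = 3)
  big$interval_s <- sample(big$interval_s)
  expect_lt(abs(correlate_step_interval(big)$r), 0.05)
  expect_error(correlate_step_interval(big[1:2, ]), "insufficient")
  flat <- make_steps(20, 1); flat$s_2d <- 1
  expect_false(correlate_step_interval(flat)$defined)
})

test_that("pooled step-vs-interval mixed model recovers planted coupling", {
  st <- make_steps(1000, 10, slope = 0.1, seed = 7)
  res <- lmm_step_vs_interval(st, "infant", "unsplit")
  b <- res[res$term == "interval", ]
  expect_gt(b$beta, 0)
  expect_lt(b$p, 0.001)
  # standardized beta equals raw beta * sd(x)/sd(y) (fixed-effects check)
  expect_error(lmm_step_vs_interval(st[st$infant_id == "inf01", ], "infant"),
               "at least 2 infants")
})

test_that("null coupling is not detected more often than nominal", {
  rej <- 0L
  for (k in 1:40) {
    st <- make_steps(150, 6, slope = 0, seed = 100 + k, shuffle = TRUE)
    res <- lmm_step_vs_interval(st, "infant", "unsplit")
    if (res$p[res$term == "interval"] < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 6) # ~nominal 2 of 40, generous head-room
})

test_that("standardized betas are raw betas rescaled by SD ratio", {
  set.seed(9)
  d <- data.frame(x = stats::rnorm(200, 5, 3), z = stats::rnorm(200))
  d$y <- 2 * d$x - 1.5 * d$z + stats::rnorm(200)
  raw <- stats::lm(y ~ x + z, d)
  std <- stats::lm(scale(y) ~ scale(x) + scale(z), d)
  expect_equal(unname(coef(std)["scale(x)"]),
               unname(coef(raw)["x"]) * stats::sd(d$x) / stats::sd(d$y),
               tolerance = 1e-10)
})

test_that("summary-feature regression requires both splits and >= 2 infants", {
  tab <- data.frame(recording = c("a", "b"), infant_id = c("i1", "i2"),
                    age_days = c(92, 184), speaker_type = "infant",
                    split = "WR", measure = "interval",
                    median = c(1, 2), p90 = c(2, 4), n_steps = 10,
                    sample_size = c(100, 120), stringsAsFactors = FALSE)
  expect_error(lmm_summary_features(tab), "WOR")
  expect_error(lmm_summary_features(tab, dv = "nonsense"), "unknown dependent")
})

test_that("two-sample KS statistic hits its extremes and calibrates", {
  a <- seq(0, 1, length.out = 50)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(a, a + 10)$D, 1)
  set.seed(12)
  rej <- sum(vapply(1:100, function(k) {
    ks_two_sample(stats::rlnorm(500), stats::rlnorm(500))$p < 0.05
  }, TRUE))
  expect_lte(rej, 7)
  expect_error(ks_two_sample(1, 1:5), "at least 2")
})

test_that("agreement measures match hand computations", {
  a <- c("CHN", "FAN", "MAN", "CHN")
  res <- agreement(a, a)
  expect_equal(res$percent_agreement, 100)
  expect_equal(res$kappa, 1)
  # one rater constant, the other split 50/50 -> chance-level kappa 0
  res <- agreement(rep("A", 100), rep(c("A", "B"), 50))
  expect_equal(res$kappa, 0)
  expect_equal(res$percent_agreement, 50)
  # printed 2x2 table (45,5; 5,45): agreement 90%, kappa 0.8
  x <- c(rep("CHN", 50), rep("FAN", 50))
  y <- c(rep("CHN", 45), rep("FAN", 5), rep("CHN", 5), rep("FAN", 45))
  res <- agreement(x, y)
  expect_equal(res$percent_agreement, 90)
  expect_equal(res$kappa, 0.8)
  expect_error(agreement(x, y[-1]), "length")
  # independent cross-check of the kappa formula
  skip_if_not_installed("e1071")
  ca <- e1071::classAgreement(table(x, y))
  expect_equal(res$kappa, ca$kappa)
})

test_that("logistic response model flags separation instead of failing", {
  ev <- code_responses(simulate_random_events(300, seed = 5))
  ev$infant_id <- rep(c("i1", "i2"), length.out = 300)
  ev$response_code[ev$speaker_label == "CHNSP"] <- "Y"
  res <- glmm_response(ev, "infant")
  expect_false(any(res$converged))
  expect_match(res$flag[1], "separation")
})
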