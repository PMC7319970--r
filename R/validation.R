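# Validation harness: oracle-equivalence, selection-accuracy,
# parameter-recovery and calibration suites. The same functions back the
# test suite, the acceptance script and analysis/05_validation.R, so the
# numbers reported anywhere are recomputed the same way.

#' Simulate an adversarial random event table
#'
#' Dense random sequences for coding-equivalence checks: gaps are a mixture
#' of sub-second and longer waits so response windows, NA separations and
#' blockers are all exercised; labels cover every speaker class including
#' `OTHER`; a few random subrecording breaks are inserted.
#'
#' @param n_events number of events.
#' @param seed RNG seed.
#' @param n_subrecordings number of subrecording blocks.
#' @return event data.frame with `pitch_z`/`amp_z` attached.
#' @export
simulate_random_events <- function(n_events = 500, seed = 1L, n_subrecordings = 3) {
  set.seed(seed)
  gaps <- ifelse(stats::runif(n_events) < 0.6,
                 stats::runif(n_events, 0, 1.3),
                 stats::rexp(n_events, 1 / 4))
  dur <- stats::runif(n_events, 0.2, 2)
  onset <- cumsum(gaps + c(0, dur[-n_events]))
  lab <- sample(c("CHNSP", "CHN_NSP", "FAN", "MAN", "OTHER"), n_events,
                replace = TRUE, prob = c(0.3, 0.1, 0.35, 0.15, 0.1))
  sub <- sort(sample.int(n_subrecordings, n_events, replace = TRUE)) - 1L
  data.frame(infant_id = "sim", age_days = 180,
             subrecording_id = sub, speaker_label = lab,
             onset_s = onset, offset_s = onset + dur,
             mean_pitch_hz = exp(stats::rnorm(n_events, 5.5, 0.3)),
             mean_amplitude_db = stats::rnorm(n_events, 60, 4),
             pitch_z = stats::rnorm(n_events), amp_z = stats::rnorm(n_events),
             stringsAsFactors = FALSE)
}

#' Response-coding oracle equivalence
#'
#' Codes `n_sequences` random event tables with both [code_responses()] and
#' the exhaustive-scan reference coder and counts mismatching codes.
#'
#' @param n_sequences number of random sequences.
#' @param n_events events per sequence.
#' @param window_s response window (s).
#' @param seed base seed (sequence k uses `seed + k`).
#' @return number of mismatched codes (0 = equivalence).
#' @export
validate_response_coding <- function(n_sequences = 1000, n_events = 500,
                                     window_s = 1.0, seed = 0L) {
  mismatches <- 0L
  for (k in seq_len(n_sequences)) {
    ev <- simulate_random_events(n_events, seed = seed + k)
    a <- code_responses(ev, window_s)$response_code
    b <- code_responses_bruteforce(ev, window_s)$response_code
    same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
    mismatches <- mismatches + sum(!same)
  }
  mismatches
}

#' AIC selection accuracy on known generators
#'
#' Draws `reps` samples of size `n` from a known family and reports the
#' fraction in which [aic_select()] picks that family.
#'
#' @param family generating family.
#' @param params generating parameters (defaults per family chosen to be
#'   clearly distinguishable at moderate n).
#' @param n sample size per replicate.
#' @param reps replicates.
#' @param seed base seed.
#' @return fraction of replicates selecting the true family.
#' @export
aic_selection_accuracy <- function(family, params = NULL, n = 5000, reps = 100,
                                   seed = 0L) {
  if (is.null(params)) {
    params <- switch(family,
      exponential = list(rate = 1),
      normal = list(mean = 5, sd = 1),
      lognormal = list(meanlog = 0.4, sdlog = 1.1),
      pareto = list(xmin = 1, alpha = 1.8))
  }
  hit <- 0L
  for (k in seq_len(reps)) {
    set.seed(seed + k)
    x <- switch(family,
      exponential = stats::rexp(n, params$rate),
      normal = stats::rnorm(n, params$mean, params$sd),
      lognormal = stats::rlnorm(n, params$meanlog, params$sdlog),
      pareto = rpareto(n, params$xmin, params$alpha))
    if (family == "normal") x <- abs(x) # keep samples positive for all four fits
    if (identical(aic_select(x)$best$family, family)) hit <- hit + 1L
  }
  hit / reps
}

#' MLE recovery error on large known samples
#'
#' Draws one sample of size `n` per family and returns the maximum absolute
#' parameter-recovery error across families (rate for exponential;
#' mean/sd for normal; meanlog/sdlog for lognormal; alpha for Pareto --
#' xmin is min-estimated and converges at rate 1/n).
#'
#' @param n sample size.
#' @param seed RNG seed.
#' @return named numeric of absolute errors per parameter.
#' @export
mle_recovery_errors <- function(n = 1e5, seed = 1L) {
  set.seed(seed)
  errs <- c()
  x <- stats::rexp(n, 2)
  errs["exponential_rate"] <- abs(fit_mle(x, "exponential")$params[["rate"]] - 2)
  x <- stats::rnorm(n, 5, 1.5)
  f <- fit_mle(x, "normal")
  errs["normal_mean"] <- abs(f$params[["mean"]] - 5)
  errs["normal_sd"] <- abs(f$params[["sd"]] - 1.5)
  x <- stats::rlnorm(n, 0.4, 1.1)
  f <- fit_mle(x, "lognormal")
  errs["lognormal_meanlog"] <- abs(f$params[["meanlog"]] - 0.4)
  errs["lognormal_sdlog"] <- abs(f$params[["sdlog"]] - 1.1)
  x <- rpareto(n, 1, 1.8)
  f <- fit_mle(x, "pareto")
  errs["pareto_alpha"] <- abs(f$params[["alpha"]] - 1.8)
  errs
}

#' Run the standard validation suite
#'
#' Executes the oracle-equivalence, selection-accuracy, parameter-recovery
#' and null-calibration checks at configurable problem sizes and returns a
#' pass/fail report with the measured numbers. Failures are reported, not
#' raised.
#'
#' @param seed master seed.
#' @param n_oracle_sequences,oracle_events oracle-equivalence problem size.
#' @param aic_n,aic_reps selection-accuracy problem size.
#' @param n_ks_reps,ks_n KS null-calibration problem size.
#' @param checks which checks to run (subset of the report's `check`
#'   column); empty selection gives an empty report.
#' @return data.frame `check, value, threshold, comparison, pass`.
#' @export
run_validation_suite <- function(seed = 1L, n_oracle_sequences = 200,
                                 oracle_events = 200, aic_n = 5000, aic_reps = 50,
                                 n_ks_reps = 100, ks_n = 500,
                                 checks = c("oracle", "aic", "mle", "ks_null")) {
  rows <- list()
  add <- function(check, value, threshold, comparison) {
    pass <- switch(comparison, le = value <= threshold, ge = value >= threshold)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, threshold = threshold,
      comparison = comparison, pass = pass, stringsAsFactors = FALSE)
  }
  if ("oracle" %in% checks) {
    add("oracle_mismatches",
        validate_response_coding(n_oracle_sequences, oracle_events, seed = seed),
        0, "le")
  }
  if ("aic" %in% checks) {
    for (fam in .VF_FAMILIES) {
      add(paste0("aic_accuracy_", fam),
          aic_selection_accuracy(fam, n = aic_n, reps = aic_reps, seed = seed),
          0.95, "ge")
    }
  }
  if ("mle" %in% checks) {
    add("mle_max_error", max(mle_recovery_errors(1e5, seed = seed)), 0.02, "le")
  }
  if ("ks_null" %in% checks) {
    set.seed(seed)
    rej <- 0L
    for (k in seq_len(n_ks_reps)) {
      if (ks_two_sample(stats::rlnorm(ks_n, 0, 1), stats::rlnorm(ks_n, 0, 1))$p < 0.05) {
        rej <- rej + 1L
      }
    }
    add("ks_null_rejection_rate", rej / n_ks_reps, 0.07, "le")
  }
  if (!length(rows)) {
    return(data.frame(check = character(), value = numeric(), threshold = numeric(),
                      comparison = character(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
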