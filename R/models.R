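# Inferential layer: per-recording correlations, pooled step-vs-interval
# mixed model, mixed-effects regressions of per-recording summary features,
# logistic mixed models of response receipt, and validation utilities
# (two-sample KS, percent agreement, Cohen's kappa).
#
# "Standardized beta" throughout: the dependent variable and all continuous
# predictors are z-scored (population SD) across the analysis table before
# fitting; the binary WR/WOR predictor stays 0/1. Linear mixed-model
# p-values use lmerTest's Satterthwaite approximation; the method and
# convergence status are recorded in every result row.

result_row <- function(model, dv, term, beta, p, n, method, converged, flag = "") {
  data.frame(model = model, dv = dv, term = term, beta = beta, p = p, n = n,
             method = method, converged = converged, flag = flag,
             stringsAsFactors = FALSE)
}

extract_lmm <- function(fit, model, dv, n) {
  co <- stats::coef(summary(fit))
  singular <- lme4::isSingular(fit)
  terms <- setdiff(rownames(co), "(Intercept)")
  do.call(rbind, lapply(terms, function(tm) {
    result_row(model, dv, tm, beta = co[tm, "Estimate"],
               p = co[tm, "Pr(>|t|)"], n = n,
               method = "lmer-satterthwaite", converged = TRUE,
               flag = if (singular) "singular" else "")
  }))
}

#' Correlation between acoustic step size and interval, one recording
#'
#' Pearson correlation between the 2-D acoustic step size and the
#' corresponding inter-vocalisation interval for one recording and speaker
#' type, with a two-sided p-value.
#'
#' @param steps step table of a single recording and speaker type.
#' @return list `r`, `p`, `n`, `defined` (FALSE when a variable has zero
#'   variance).
#' @export
correlate_step_interval <- function(steps) {
  n <- nrow(steps)
  if (n < 3) vf_stop("insufficient data: need at least 3 steps, got %d", n)
  if (popsd(steps$s_2d) == 0 || popsd(steps$interval_s) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  ct <- stats::cor.test(steps$s_2d, steps$interval_s, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Per-recording correlations across a cohort
#'
#' Runs [correlate_step_interval()] for every recording x speaker type and
#' reports the cohort aggregation (mean and median r and p) per speaker.
#'
#' @param steps pooled step table ([cohort_steps()]).
#' @return list with `by_recording` and `aggregate` data.frames.
#' @export
correlations_by_recording <- function(steps) {
  rows <- list()
  for (sp in unique(steps$speaker_type)) {
    for (rec in unique(steps$recording[steps$speaker_type == sp])) {
      sel <- steps$speaker_type == sp & steps$recording == rec
      if (sum(sel) < 3) next
      res <- correlate_step_interval(steps[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        recording = rec, speaker_type = sp, r = res$r, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) vf_stop("no recording had enough steps for correlation")
  br <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(br, br$speaker_type), function(d) {
    data.frame(speaker_type = d$speaker_type[1],
               mean_r = mean(d$r, na.rm = TRUE), median_r = stats::median(d$r, na.rm = TRUE),
               mean_p = mean(d$p, na.rm = TRUE), median_p = stats::median(d$p, na.rm = TRUE),
               mean_n = mean(d$n), n_recordings = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(by_recording = br, aggregate = agg)
}

#' Pooled mixed model: acoustic step size vs interval
#'
#' `s_2d ~ interval + age + (1 | infant)` over all steps of one speaker
#' type pooled across recordings, with standardized coefficients. Can be
#' restricted to WR-only or WOR-only steps.
#'
#' @param steps pooled step table.
#' @param speaker_type `"infant"` or `"adult"`.
#' @param split `"unsplit"` (all steps, no interval filter), `"WR"` or
#'   `"WOR"` (retained steps of that class).
#' @return data.frame of standardized coefficients (one row per term).
#' @export
lmm_step_vs_interval <- function(steps, speaker_type = c("infant", "adult"),
                                 split = c("unsplit", "WR", "WOR")) {
  speaker_type <- match.arg(speaker_type)
  split <- match.arg(split)
  sel <- steps$speaker_type == speaker_type
  if (split != "unsplit") {
    sel <- sel & steps$in_split_analysis & steps$split_class == split
  }
  d <- steps[sel, , drop = FALSE]
  if (length(unique(d$infant_id)) < 2) {
    vf_stop("random effect undefined: need at least 2 infants")
  }
  df <- data.frame(
    y = zscore(d$s_2d, "s_2d"),
    interval = zscore(d$interval_s, "interval"),
    age = zscore(d$age_days, "age"),
    infant_id = d$infant_id)
  fit <- lmerTest::lmer(y ~ interval + age + (1 | infant_id), data = df,
                        REML = TRUE)
  extract_lmm(fit, model = paste0("step_vs_interval_", speaker_type, "_", split),
              dv = "s_2d", n = nrow(df))
}

#' Mixed-effects regression of per-recording summary features
#'
#' The central design: `dv ~ response + age + sample_size +
#' (1 | infant_id)` over the WR/WOR summary rows of one speaker type and
#' measure, where `response` is 1 for WR rows and 0 for WOR rows. The
#' interaction between response and age is excluded by default and
#' available behind `interaction`; `include_sample_size` drops the
#' sample-size covariate. Continuous variables are standardized; the
#' response indicator stays 0/1.
#'
#' @param summary_table from [summary_feature_table()].
#' @param dv dependent variable column (`"median"`, `"p90"`, or a fitted
#'   parameter such as `"meanlog"`, `"sdlog"`, `"xmin"`, `"alpha"`,
#'   `"rate"`). For parameter dvs only rows with `use_params` are used.
#' @param speaker_type,measure which cell of the summary table to model.
#' @param include_sample_size include the sample-size fixed effect.
#' @param interaction include a response x age interaction term.
#' @return data.frame of standardized coefficients.
#' @export
lmm_summary_features <- function(summary_table, dv = "median",
                                 speaker_type = "infant", measure = "interval",
                                 include_sample_size = TRUE,
                                 interaction = FALSE) {
  d <- summary_table[summary_table$speaker_type == speaker_type &
                       summary_table$measure == measure, , drop = FALSE]
  if (!dv %in% names(d)) vf_stop("unknown dependent variable '%s'", dv)
  if (dv %in% c("meanlog", "sdlog", "xmin", "alpha", "rate")) {
    d <- d[d$use_params & !is.na(d[[dv]]), , drop = FALSE]
  }
  if (!all(c("WR", "WOR") %in% d$split)) {
    vf_stop("both WR and WOR rows are required for the response effect")
  }
  if (length(unique(d$infant_id)) < 2) {
    vf_stop("random effect undefined: need at least 2 infants")
  }
  df <- data.frame(
    y = zscore(d[[dv]], dv),
    response = as.numeric(d$split == "WR"),
    age = zscore(d$age_days, "age"),
    n_sz = zscore(d$sample_size, "sample_size"),
    infant_id = d$infant_id)
  form <- if (interaction) {
    if (include_sample_size) y ~ response * age + n_sz + (1 | infant_id)
    else y ~ response * age + (1 | infant_id)
  } else {
    if (include_sample_size) y ~ response + age + n_sz + (1 | infant_id)
    else y ~ response + age + (1 | infant_id)
  }
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  out <- extract_lmm(fit, model = sprintf("summary_%s_%s_%s", speaker_type, measure, dv),
                     dv = dv, n = nrow(df))
  out$term[out$term == "n_sz"] <- "sample_size"
  out
}

#' Logistic mixed model of response receipt
#'
#' `response ~ pitch_z + amp_z + age (+ preceding step sizes) +
#' (1 | infant_id)` over coded events of the receiving speaker type, with
#' Y coded 1, N coded 0 and NA-coded events excluded. With
#' `include_step_predictors`, the non-directional step sizes in pitch,
#' amplitude and time from the previous same-stream vocalisation are added
#' (events with no predecessor in their subrecording are dropped).
#'
#' @param coded named list of coded event data.frames, or one pooled
#'   data.frame of coded events from several recordings.
#' @param receiver `"infant"` (CHNSP events receiving adult responses) or
#'   `"adult"` (FAN/MAN events receiving infant responses).
#' @param include_step_predictors add preceding-step fixed effects.
#' @param nagq integration points for [lme4::glmer()] (1 = Laplace).
#' @return data.frame of standardized coefficients; a complete-separation
#'   outcome is reported via the `flag` column rather than an error.
#' @export
glmm_response <- function(coded, receiver = c("infant", "adult"),
                          include_step_predictors = FALSE, nagq = 1L) {
  receiver <- match.arg(receiver)
  recs <- if (is.data.frame(coded)) list(coded) else coded
  labs <- if (receiver == "infant") "CHNSP" else c("FAN", "MAN")
  pieces <- lapply(recs, function(ev) {
    sel <- which(ev$speaker_label %in% labs & ev$response_code %in% c("Y", "N"))
    if (!length(sel)) return(NULL)
    d <- data.frame(
      response = as.numeric(ev$response_code[sel] == "Y"),
      pitch = ev$pitch_z[sel], amp = ev$amp_z[sel],
      age_days = ev$age_days[sel], infant_id = ev$infant_id[sel],
      stringsAsFactors = FALSE)
    if (include_step_predictors) {
      # previous same-stream event within the subrecording (NA coded or not)
      stream <- which(ev$speaker_label %in% labs)
      prev <- rep(NA_integer_, nrow(ev))
      by_sub <- split(stream, ev$subrecording_id[stream])
      for (ix in by_sub) if (length(ix) > 1) prev[ix[-1]] <- ix[-length(ix)]
      p <- prev[sel]
      d$step_pitch <- abs(ev$pitch_z[sel] - ev$pitch_z[p])
      d$step_amp <- abs(ev$amp_z[sel] - ev$amp_z[p])
      d$step_time <- ev$onset_s[sel] - ev$offset_s[p]
      d <- d[!is.na(p), , drop = FALSE]
    }
    d
  })
  d <- do.call(rbind, pieces)
  if (is.null(d) || !nrow(d)) vf_stop("no Y/N-coded events for receiver '%s'", receiver)
  if (length(unique(d$infant_id)) < 2) {
    vf_stop("random effect undefined: need at least 2 infants")
  }
  model_id <- sprintf("response_%s%s", receiver,
                      if (include_step_predictors) "_steps" else "")
  if (length(unique(d$response)) < 2) {
    return(result_row(model_id, "response", "(none)", NA_real_, NA_real_,
                      nrow(d), sprintf("glmer-laplace-nagq%d", nagq),
                      converged = FALSE, flag = "separation"))
  }
  d$pitch <- zscore(d$pitch, "pitch")
  d$amp <- zscore(d$amp, "amplitude")
  d$age <- zscore(d$age_days, "age")
  form <- if (include_step_predictors) {
    d$step_pitch <- zscore(d$step_pitch, "step_pitch")
    d$step_amp <- zscore(d$step_amp, "step_amp")
    d$step_time <- zscore(d$step_time, "step_time")
    response ~ pitch + amp + age + step_pitch + step_amp + step_time + (1 | infant_id)
  } else {
    response ~ pitch + amp + age + (1 | infant_id)
  }
  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial, nAGQ = nagq),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(summary(fit))
  terms <- setdiff(rownames(co), "(Intercept)")
  separation <- any(abs(co[, "Estimate"]) > 15)
  flag <- paste(c(if (separation) "separation",
                  if (length(warn)) "convergence-warning"), collapse = ";")
  out <- do.call(rbind, lapply(terms, function(tm) {
    result_row(model_id, "response", tm, beta = co[tm, "Estimate"],
               p = co[tm, "Pr(>|z|)"], n = nrow(d),
               method = sprintf("glmer-laplace-nagq%d", nagq),
               converged = !length(warn), flag = flag)
  }))
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper over [stats::ks.test()] (exact or asymptotic p as chosen by
#' the underlying implementation).
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @return list `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) vf_stop("both samples need at least 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Inter-rater agreement: percent agreement and Cohen's kappa
#'
#' @param labels_a,labels_b equal-length aligned label vectors.
#' @return list with `percent_agreement` (0-100), `kappa`, and the
#'   confusion `table`.
#' @export
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    vf_stop("label lists differ in length (%d vs %d)", length(labels_a), length(labels_b))
  }
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) { if (po == 1) 1 else NA_real_ } else (po - pe) / (1 - pe)
  list(percent_agreement = 100 * po, kappa = kappa, table = tab)
}
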