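# Synthetic cohort generator. Produces day-long, speaker-labelled
# vocalisation tables with planted, recoverable statistical structure:
# per-speaker interval renewal processes, a bounded random walk in a 2-D
# pitch-amplitude space, a 1-s response-contingency whose probability is a
# logistic function of the vocalisation's acoustics and infant age,
# post-response shortening of the receiver's next interval/step
# (area-restricted search), occasional non-speech infant events, and
# recorder pauses that create subrecording boundaries.
#
# The generator is test scaffolding with explicit, serialisable parameters;
# it makes no claim about the generative process behind real recordings.

.SPEAKER_LABELS <- c("CHNSP", "CHN_NSP", "FAN", "MAN", "OTHER")

#' Specify the synthetic vocalisation process
#'
#' Bundles every tunable parameter of the synthetic generator. Defaults
#' emulate the qualitative structure reported for real daylong recordings:
#' lognormal infant inter-vocalisation intervals, heavy-tailed (Pareto)
#' adult intervals, lognormal acoustic steps (so 2-D step sizes come out
#' approximately lognormal), response probabilities that depend on the
#' vocalisation's pitch, amplitude and infant age, and shorter intervals
#' immediately after a received response.
#'
#' @param interval_family per-speaker interval distributions; a list with
#'   elements `infant` and `adult`, each `list(family =, ...params)` with
#'   family one of `"exponential"`, `"lognormal"`, `"pareto"` (seconds).
#'   Pareto interval families must have `alpha > 1` (finite mean).
#' @param post_response_interval_scale positive multiplier applied to the
#'   interval draw that follows a received response (values `< 1` plant an
#'   area-restricted-search effect).
#' @param acoustic_step_family distribution of per-dimension acoustic step
#'   magnitudes (internal z-like units); family one of `"exponential"`,
#'   `"lognormal"`, `"normal"` (folded).
#' @param post_response_acoustic_scale positive multiplier on the acoustic
#'   step magnitude following a received response.
#' @param response_logit_coefs list with elements `infant` and `adult`
#'   (the *receiving* speaker type), each a numeric vector
#'   `c(intercept, pitch, amplitude, age)`; pitch/amplitude coefficients are
#'   per internal acoustic unit, the age coefficient per standardised day
#'   (see [derive_seed()] docs for the fixed anchor). The probability that a
#'   vocalisation receives a reply is `plogis(intercept + pitch * f +
#'   amplitude * d + age * a)`.
#' @param duration_mean mean utterance duration (s) per speaker,
#'   `c(infant =, adult =)`; durations are drawn lognormally around these.
#' @param nonspeech_infant_rate rate (events/hour) of non-speech infant
#'   (`CHN_NSP`) events, inserted to exercise the NA coding rule.
#' @param pitch_missing_prob probability that an event has no detectable
#'   pitch (its pitch field is written as missing).
#' @param pause_spec recorder pauses: `list(n =, length_s =)`; each pause
#'   deletes overlapping events and starts a new subrecording.
#' @param age_effects monotone age transforms applied by [generate_cohort()]:
#'   `list(infant_interval =, adult_interval =, acoustic_step =)`, each a
#'   log-scale shift per 100 days of age relative to the cohort anchor
#'   (lognormal families shift `meanlog`; exponential families scale the
#'   mean; Pareto families scale `xmin`).
#' @return an object of class `vf_process_spec`.
#' @seealso [cohort_spec()], [generate_recording()], [generate_cohort()]
#' @export
process_spec <- function(
    interval_family = list(
      infant = list(family = "lognormal", meanlog = 2.3, sdlog = 1.6),
      adult = list(family = "pareto", xmin = 0.5, alpha = 1.08)),
    post_response_interval_scale = 0.7,
    acoustic_step_family = list(family = "lognormal", meanlog = -0.8, sdlog = 0.7),
    post_response_acoustic_scale = 1.0,
    response_logit_coefs = list(
      infant = c(intercept = -1.1, pitch = -0.32, amplitude = 0.17, age = -0.16),
      adult = c(intercept = -1.4, pitch = 0.23, amplitude = 0.45, age = -0.01)),
    duration_mean = c(infant = 1.0, adult = 1.5),
    nonspeech_infant_rate = 10,
    pitch_missing_prob = 0.02,
    pause_spec = list(n = 1, length_s = 600),
    age_effects = list(infant_interval = 0, adult_interval = 0, acoustic_step = 0)) {
  spec <- list(
    interval_family = interval_family,
    post_response_interval_scale = post_response_interval_scale,
    acoustic_step_family = acoustic_step_family,
    post_response_acoustic_scale = post_response_acoustic_scale,
    response_logit_coefs = response_logit_coefs,
    duration_mean = duration_mean,
    nonspeech_infant_rate = nonspeech_infant_rate,
    pitch_missing_prob = pitch_missing_prob,
    pause_spec = pause_spec,
    age_effects = age_effects)
  class(spec) <- "vf_process_spec"
  validate_process_spec(spec)
  spec
}

validate_process_spec <- function(spec) {
  for (who in c("infant", "adult")) {
    fam <- spec$interval_family[[who]]
    if (is.null(fam$family)) vf_stop("interval_family$%s must name a family", who)
    check_family(fam$family, fam[setdiff(names(fam), "family")])
    if (identical(fam$family, "normal")) {
      vf_stop("interval family for %s cannot be normal", who)
    }
    if (identical(fam$family, "pareto") && fam$alpha <= 1) {
      vf_stop("pareto interval exponent alpha must be > 1 (finite mean); got %s",
              format(fam$alpha))
    }
    co <- spec$response_logit_coefs[[who]]
    if (!is.numeric(co) || length(co) != 4) {
      vf_stop("response_logit_coefs$%s must be numeric length 4 (intercept, pitch, amplitude, age)", who)
    }
  }
  ac <- spec$acoustic_step_family
  check_family(ac$family, ac[setdiff(names(ac), "family")])
  if (!is_scalar_pos(spec$post_response_interval_scale) ||
      !is_scalar_pos(spec$post_response_acoustic_scale)) {
    vf_stop("post-response scales must be positive")
  }
  if (!all(c("infant", "adult") %in% names(spec$duration_mean)) ||
      any(spec$duration_mean <= 0)) {
    vf_stop("duration_mean must be positive and name infant and adult")
  }
  if (!is.numeric(spec$nonspeech_infant_rate) || spec$nonspeech_infant_rate < 0) {
    vf_stop("nonspeech_infant_rate must be >= 0")
  }
  if (spec$pitch_missing_prob < 0 || spec$pitch_missing_prob >= 1) {
    vf_stop("pitch_missing_prob must be in [0, 1)")
  }
  ps <- spec$pause_spec
  if (!is.numeric(ps$n) || ps$n < 0 || ps$n != round(ps$n) || ps$length_s < 0) {
    vf_stop("pause_spec must give a non-negative integer n and length_s >= 0")
  }
  invisible(spec)
}

#' Specify a synthetic cohort
#'
#' @param n_infants number of infants.
#' @param ages_days recording ages (days) shared by every infant; must lie
#'   in `[30, 550]` (roughly 1-18 months).
#' @param recording_length_s length of each recording in seconds
#'   (at most 16 h, the recorder's capacity).
#' @param events_per_recording hard cap on generated speech events per
#'   recording (a safety bound for heavy-tailed interval draws, not a
#'   target that is forced).
#' @param master_seed integer master seed; per-recording seeds are derived
#'   with [derive_seed()].
#' @return an object of class `vf_cohort_spec`.
#' @export
cohort_spec <- function(n_infants = 15,
                        ages_days = c(92, 184, 276, 548),
                        recording_length_s = 10 * 3600,
                        events_per_recording = 25000,
                        master_seed = 1L) {
  if (!is_count(n_infants)) vf_stop("n_infants must be a positive integer")
  if (anyDuplicated(ages_days)) vf_stop("duplicate infant/age combinations in ages_days")
  if (any(ages_days < 30 | ages_days > 550)) {
    vf_stop("ages_days must lie within [30, 550] days")
  }
  if (!is_scalar_pos(recording_length_s) || recording_length_s > 16 * 3600) {
    vf_stop("recording_length_s must be positive and at most 16 hours")
  }
  if (!is_count(events_per_recording)) vf_stop("events_per_recording must be a positive integer")
  structure(list(n_infants = as.integer(n_infants),
                 ages_days = as.numeric(ages_days),
                 recording_length_s = recording_length_s,
                 events_per_recording = as.integer(events_per_recording),
                 master_seed = as.integer(master_seed)),
            class = "vf_cohort_spec")
}

#' Apply planted age effects to a process specification
#'
#' Shifts the location of the interval and acoustic-step families as a
#' monotone function of infant age: `delta = slope * (age - anchor) / 100`
#' on the log scale, where the anchor is the fixed age centre used
#' throughout the generator. Lognormal families shift `meanlog` by `delta`;
#' exponential families divide `rate` by `exp(delta)`; Pareto families
#' multiply `xmin` by `exp(delta)`.
#'
#' @param spec a [process_spec()].
#' @param age_days infant age in days.
#' @return a `vf_process_spec` with age-adjusted parameters.
#' @export
apply_age_effects <- function(spec, age_days) {
  shift_family <- function(fam, delta) {
    if (delta == 0) return(fam)
    switch(fam$family,
      lognormal = { fam$meanlog <- fam$meanlog + delta; fam },
      exponential = { fam$rate <- fam$rate / exp(delta); fam },
      pareto = { fam$xmin <- fam$xmin * exp(delta); fam },
      normal = { fam$mean <- fam$mean * exp(delta); fam })
  }
  centred <- (age_days - .AGE_CENTER_DAYS) / 100
  ae <- spec$age_effects
  spec$interval_family$infant <- shift_family(spec$interval_family$infant,
                                              ae$infant_interval * centred)
  spec$interval_family$adult <- shift_family(spec$interval_family$adult,
                                             ae$adult_interval * centred)
  spec$acoustic_step_family <- shift_family(spec$acoustic_step_family,
                                            ae$acoustic_step * centred)
  spec
}

# raw acoustic anchors: common slope, speaker-specific baselines, so pooled
# z-scores retain realistic infant/adult offsets
.RAW_LOGPITCH_BASE <- c(infant = log(320), adult = log(190))
.RAW_LOGPITCH_SCALE <- 0.35
.RAW_AMP_BASE <- c(infant = 62, adult = 56)
.RAW_AMP_SCALE <- 4

#' Generate one synthetic day-long recording
#'
#' Simulates interleaved infant (`CHNSP`) and adult (`FAN`/`MAN`) streams.
#' Each stream is a renewal process in time (interval drawn from its family,
#' measured offset-to-next-onset) and a reflected random walk in a 2-D
#' acoustic space. After every vocalisation, a reply by the other speaker
#' type is inserted with probability `plogis(coefs %*% (1, pitch, amp, age))`
#' at an onset uniform in `(0, 1]` s after the offset; when a vocalisation
#' received a reply, the *receiving* speaker's next interval and acoustic
#' step are multiplied by the post-response scales. Non-speech infant
#' events are sprinkled in at a low rate, events overlapping recorder
#' pauses are deleted, and pauses delimit subrecordings. Events never
#' overlap and onsets strictly increase.
#'
#' @param spec a [process_spec()] (already age-adjusted if that is wanted;
#'   [generate_cohort()] applies [apply_age_effects()] itself).
#' @param infant_id infant identifier string.
#' @param age_days infant age in days (enters the response logit).
#' @param recording_length_s recording length in seconds.
#' @param seed integer seed for this recording.
#' @param max_events cap on generated speech events.
#' @return a data.frame of events in the segment-table layout
#'   (`infant_id, age_days, subrecording_id, speaker_label, onset_s,
#'   offset_s, mean_pitch_hz, mean_amplitude_db`) with attribute `"truth"`
#'   recording the parameters actually used.
#' @export
generate_recording <- function(spec, infant_id = "inf01", age_days = 180,
                               recording_length_s = 10 * 3600, seed = 1L,
                               max_events = 25000) {
  validate_process_spec(spec)
  if (!is_scalar_pos(recording_length_s)) vf_stop("recording_length_s must be positive")
  set.seed(seed)
  L <- recording_length_s
  a_std <- age_std(age_days)

  fam_i <- spec$interval_family
  fam_ac <- spec$acoustic_step_family
  ac_par <- fam_ac[setdiff(names(fam_ac), "family")]
  int_par <- lapply(fam_i, function(f) f[setdiff(names(f), "family")])
  dm <- spec$duration_mean
  # lognormal durations with sdlog 0.5 and the requested mean
  dur_meanlog <- log(dm) - 0.5^2 / 2
  coefs <- spec$response_logit_coefs

  # quick feasibility check: expected first onsets must fit
  mean_interval <- function(f) {
    p <- f[setdiff(names(f), "family")]
    switch(f$family,
      exponential = 1 / p$rate,
      lognormal = exp(p$meanlog + p$sdlog^2 / 2),
      pareto = p$alpha * p$xmin / (p$alpha - 1))
  }
  if (min(mean_interval(fam_i$infant), mean_interval(fam_i$adult)) > L) {
    vf_stop("infeasible spec: expected interval exceeds recording length (%s s)", format(L))
  }

  cap <- max_events
  n_ev <- 0L
  onset <- numeric(cap); offset <- numeric(cap)
  pit <- numeric(cap); amp <- numeric(cap)
  who_i <- integer(cap) # 1 infant, 2 adult
  masked <- logical(cap)

  streams <- c("infant", "adult")
  pos <- list(infant = stats::rnorm(2), adult = stats::rnorm(2))
  received <- c(infant = FALSE, adult = FALSE)
  next_on <- c(infant = sample_interval(fam_i$infant$family, int_par$infant),
               adult = sample_interval(fam_i$adult$family, int_par$adult))

  while (n_ev < cap) {
    s_idx <- which.min(next_on)
    on <- next_on[[s_idx]]
    if (!is.finite(on) || on >= L) {
      next_on[[s_idx]] <- Inf
      if (all(!is.finite(next_on))) break
      next
    }
    s <- streams[s_idx]
    # strict global onset ordering (ties are nudged, not reordered)
    if (n_ev > 0L && on <= onset[n_ev]) on <- onset[n_ev] + 1e-3
    dur <- stats::rlnorm(1, dur_meanlog[[s]], 0.5)
    off <- on + dur
    if (on >= L || off > L) {
      next_on[[s_idx]] <- Inf
      if (all(!is.finite(next_on))) break
      next
    }
    # interruption semantics: a newly starting vocalisation truncates the
    # ongoing one; near-total truncations count as masked (undetected)
    if (n_ev > 0L && offset[n_ev] > on) {
      offset[n_ev] <- on - 1e-4
      if (offset[n_ev] - onset[n_ev] < 0.05) masked[n_ev] <- TRUE
    }

    sc_ac <- if (received[[s_idx]]) spec$post_response_acoustic_scale else 1
    stp <- sample_step_magnitude(fam_ac$family, ac_par, 2) * sc_ac *
      sample(c(-1, 1), 2, replace = TRUE)
    p_new <- reflect_into(pos[[s_idx]] + stp, -3, 3)
    pos[[s_idx]] <- p_new

    n_ev <- n_ev + 1L
    onset[n_ev] <- on; offset[n_ev] <- off
    pit[n_ev] <- p_new[1]; amp[n_ev] <- p_new[2]
    who_i[n_ev] <- s_idx

    co <- coefs[[s]]
    p_resp <- stats::plogis(co[1] + co[2] * p_new[1] + co[3] * p_new[2] + co[4] * a_std)
    got <- stats::runif(1) < p_resp
    if (got) {
      r_on <- off + stats::runif(1)
      o_idx <- 3L - s_idx
      if (r_on < next_on[[o_idx]]) next_on[[o_idx]] <- r_on
    }
    isc <- if (got) spec$post_response_interval_scale else 1
    next_on[[s_idx]] <- off +
      sample_interval(fam_i[[s]]$family, int_par[[s]]) * isc
    received[[s_idx]] <- got
  }

  keep <- which(!masked[seq_len(n_ev)])
  ev <- data.frame(
    onset_s = onset[keep], offset_s = offset[keep],
    pitch_coord = pit[keep], amp_coord = amp[keep],
    speaker = streams[who_i[keep]],
    stringsAsFactors = FALSE)

  # adult gender labels
  lab <- ifelse(ev$speaker == "infant", "CHNSP",
                ifelse(stats::runif(nrow(ev)) < 0.8, "FAN", "MAN"))
  ev$speaker_label <- lab

  # non-speech infant events, rejected if they would overlap anything
  n_nsp <- stats::rpois(1, spec$nonspeech_infant_rate * L / 3600)
  if (n_nsp > 0) {
    cand_on <- stats::runif(n_nsp, 0, L)
    cand_dur <- stats::rlnorm(n_nsp, log(0.8) - 0.125, 0.5)
    cand_pit <- stats::rnorm(n_nsp); cand_amp <- stats::rnorm(n_nsp)
    ok <- logical(n_nsp)
    for (k in seq_len(n_nsp)) {
      o1 <- cand_on[k]; o2 <- o1 + cand_dur[k]
      if (o2 > L) next
      i <- findInterval(o1, ev$onset_s)
      clear <- (i == 0 || ev$offset_s[i] <= o1) &&
        (i >= nrow(ev) || ev$onset_s[i + 1] >= o2)
      ok[k] <- clear
    }
    if (any(ok)) {
      nsp <- data.frame(onset_s = cand_on[ok], offset_s = cand_on[ok] + cand_dur[ok],
                        pitch_coord = cand_pit[ok], amp_coord = cand_amp[ok],
                        speaker = "infant", speaker_label = "CHN_NSP",
                        stringsAsFactors = FALSE)
      # rejection against earlier-accepted candidates
      nsp <- nsp[order(nsp$onset_s), , drop = FALSE]
      if (nrow(nsp) > 1) {
        keep2 <- c(TRUE, nsp$onset_s[-1] >= cummax(nsp$offset_s[-nrow(nsp)]))
        nsp <- nsp[keep2, , drop = FALSE]
      }
      ev <- rbind(ev, nsp)
      ev <- ev[order(ev$onset_s), , drop = FALSE]
    }
  }

  # recorder pauses -> delete overlapped events, split subrecordings
  n_pause <- spec$pause_spec$n
  pause_len <- spec$pause_spec$length_s
  pause_start <- numeric(0)
  if (n_pause > 0 && pause_len > 0 && nrow(ev) > 0) {
    anchors <- (seq_len(n_pause) / (n_pause + 1)) * L
    pause_start <- sort(anchors + stats::runif(n_pause, -0.05 * L, 0.05 * L))
    pause_start <- pmin(pmax(pause_start, 0), L - pause_len)
    hit <- rep(FALSE, nrow(ev))
    for (psn in pause_start) {
      hit <- hit | (ev$onset_s < psn + pause_len & ev$offset_s > psn)
    }
    ev <- ev[!hit, , drop = FALSE]
  }
  ev$subrecording_id <- if (length(pause_start)) {
    findInterval(ev$onset_s, pause_start + pause_len / 2)
  } else rep(0L, nrow(ev))

  # raw acoustics; pitch occasionally undetected
  base_lp <- .RAW_LOGPITCH_BASE[ev$speaker]
  base_am <- .RAW_AMP_BASE[ev$speaker]
  mean_pitch_hz <- exp(base_lp + .RAW_LOGPITCH_SCALE * ev$pitch_coord)
  mean_amplitude_db <- base_am + .RAW_AMP_SCALE * ev$amp_coord
  miss <- stats::runif(nrow(ev)) < spec$pitch_missing_prob
  mean_pitch_hz[miss] <- NA_real_

  out <- data.frame(
    infant_id = rep(infant_id, nrow(ev)),
    age_days = rep(age_days, nrow(ev)),
    subrecording_id = as.integer(ev$subrecording_id),
    speaker_label = ev$speaker_label,
    onset_s = ev$onset_s,
    offset_s = ev$offset_s,
    mean_pitch_hz = mean_pitch_hz,
    mean_amplitude_db = mean_amplitude_db,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  truth <- c(
    seed = seed, age_days = age_days,
    recording_length_s = L,
    infant_interval_family = fam_i$infant$family,
    unlist(int_par$infant),
    adult_interval_family = fam_i$adult$family,
    adult = unlist(int_par$adult),
    acoustic_family = fam_ac$family, unlist(ac_par),
    post_response_interval_scale = spec$post_response_interval_scale,
    post_response_acoustic_scale = spec$post_response_acoustic_scale,
    infant_logit = coefs$infant, adult_logit = coefs$adult,
    n_events = nrow(out),
    n_infant = sum(out$speaker_label == "CHNSP"),
    n_adult = sum(out$speaker_label %in% c("FAN", "MAN")))
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic cohort of recordings
#'
#' One recording per infant x age. Per-recording seeds are derived
#' deterministically from the master seed and the infant id / age, and the
#' planted age effects in `spec$age_effects` are applied before each
#' recording is generated.
#'
#' @param cohort a [cohort_spec()].
#' @param spec a [process_spec()].
#' @return list with `recordings` (named list of event tables) and `truth`
#'   (data.frame of planted parameters, one row per recording).
#' @export
generate_cohort <- function(cohort = cohort_spec(), spec = process_spec()) {
  stopifnot(inherits(cohort, "vf_cohort_spec"))
  validate_process_spec(spec)
  ids <- sprintf("inf%02d", seq_len(cohort$n_infants))
  recs <- list()
  truth_rows <- list()
  for (id in ids) {
    for (age in cohort$ages_days) {
      key <- sprintf("%s_%03d", id, as.integer(age))
      if (key %in% names(recs)) vf_stop("duplicate infant/age combination: %s", key)
      sp <- apply_age_effects(spec, age)
      sd_rec <- derive_seed(cohort$master_seed, id, age)
      rec <- generate_recording(sp, infant_id = id, age_days = age,
                                recording_length_s = cohort$recording_length_s,
                                seed = sd_rec,
                                max_events = cohort$events_per_recording)
      recs[[key]] <- rec
      tr <- attr(rec, "truth")
      truth_rows[[key]] <- data.frame(recording = key, infant_id = id,
                                      age_days = age,
                                      parameter = names(tr),
                                      value = unname(as.character(tr)),
                                      stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(recordings = recs, truth = truth)
}

#' Write / read planted-truth parameters
#'
#' Flat key-value text serialisation (`recording.parameter=value`, one per
#' line) of the parameters the generator actually used, sufficient to score
#' parameter recovery later.
#'
#' @param truth the `truth` data.frame from [generate_cohort()].
#' @param path file path.
#' @return `read_planted_truth` returns the truth data.frame.
#' @export
write_planted_truth <- function(truth, path) {
  lines <- sprintf("%s.%s=%s", truth$recording, truth$parameter, truth$value)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_planted_truth
#' @export
read_planted_truth <- function(path) {
  lines <- readLines(path)
  eq <- regexpr("=", lines, fixed = TRUE)
  key <- substr(lines, 1, eq - 1)
  value <- substr(lines, eq + 1, nchar(lines))
  dot <- regexpr(".", key, fixed = TRUE)
  data.frame(recording = substr(key, 1, dot - 1),
             parameter = substr(key, dot + 1, nchar(key)),
             value = value, stringsAsFactors = FALSE)
}
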