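# Hand-enumerated 12-event toy recording exercising every coding branch:
# Y, N, NA, an uncoded CHN_NSP event, a response-window boundary hit
# (onset exactly offset + 1), a sub-1 s interval, an interval exactly 1 s
# (retention-filter boundary) and a subrecording break.
#
# Raw acoustics are chosen so the pooled (11 coded events; the CHN_NSP is
# excluded from pooling) statistics are hand-computable:
#   log-pitch mean 5.5, population var 1.38/11
#   amplitude mean 58,  population var 122/11

toy_events <- function() {
  lp <- c(5.8, 5.2, 5.9, 5.5, 5.1, 6.0, 5.3, 4.9, 5.7, 5.8, 5.2, 5.6)
  am <- c(60, 55, 62, 58, 54, 63, 56, 52, 61, 59, 57, 59)
  data.frame(
    infant_id = "toy01",
    age_days = 120,
    subrecording_id = c(rep(0L, 9), rep(1L, 3)),
    speaker_label = c("CHNSP", "FAN", "CHNSP", "CHN_NSP", "FAN", "CHNSP",
                      "FAN", "MAN", "CHNSP", "CHNSP", "FAN", "CHNSP"),
    onset_s = c(1.0, 1.8, 3.0, 4.2, 4.8, 5.5, 7.5, 8.4, 9.0, 100.0, 100.7, 101.5),
    offset_s = c(1.5, 2.4, 3.6, 4.6, 5.3, 6.0, 8.0, 8.9, 9.4, 100.5, 101.2, 102.0),
    mean_pitch_hz = exp(lp),
    mean_amplitude_db = am,
    pitch_missing = FALSE,
    stringsAsFactors = FALSE)
}

toy_expected_codes <- function() {
  c("Y", "Y", "NA", NA, "Y", "N", "NA", "Y", "N", "Y", "Y", "N")
}

# expected step table under the default conventions (window 1 s, "gt"
# retention filter); z-differences from the hand-derived pooled SDs
toy_expected_steps <- function() {
  sd_lp <- sqrt(1.38 / 11)
  sd_am <- sqrt(122 / 11)
  inf <- data.frame(
    speaker_type = "infant",
    subrecording_id = c(0L, 0L, 0L, 1L),
    interval_s = c(1.5, 1.9, 3.0, 1.0),
    d_pitch = c(0.1, 0.1, 0.3, 0.2) / sd_lp,
    d_amp = c(2, 1, 2, 0) / sd_am,
    split_class = c("WR", "excluded_NA", "WOR", "WR"),
    in_split_analysis = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ad <- data.frame(
    speaker_type = "adult",
    subrecording_id = c(0L, 0L, 0L),
    interval_s = c(2.4, 2.2, 0.4),
    d_pitch = c(0.1, 0.2, 0.4) / sd_lp,
    d_amp = c(1, 2, 4) / sd_am,
    split_class = c("WR", "WR", "excluded_NA"),
    in_split_analysis = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- rbind(inf, ad)
  out$s_2d <- sqrt(out$d_pitch^2 + out$d_amp^2)
  out
}

# a quiet process spec with no planted structure: no responses, no pauses,
# no non-speech events -- intervals reach the fitter untouched
quiet_spec <- function(infant_family = list(family = "lognormal", meanlog = 1.0, sdlog = 0.8),
                       adult_family = list(family = "lognormal", meanlog = 12, sdlog = 0.1)) {
  process_spec(
    interval_family = list(infant = infant_family, adult = adult_family),
    post_response_interval_scale = 1,
    post_response_acoustic_scale = 1,
    response_logit_coefs = list(
      infant = c(intercept = -1e9, pitch = 0, amplitude = 0, age = 0),
      adult = c(intercept = -1e9, pitch = 0, amplitude = 0, age = 0)),
    nonspeech_infant_rate = 0,
    pitch_missing_prob = 0,
    pause_spec = list(n = 0, length_s = 0))
}

# fully uncoupled null for type-I calibration: no response insertion at
# all (codes arise only from chance collisions), memoryless adult timing so
# chance codes are serially independent, scales 1, zero coefficients
uncoupled_null_spec <- function() {
  process_spec(
    interval_family = list(
      infant = list(family = "lognormal", meanlog = 2.3, sdlog = 1.6),
      adult = list(family = "exponential", rate = 1 / 6.75)),
    post_response_interval_scale = 1,
    post_response_acoustic_scale = 1,
    response_logit_coefs = list(
      infant = c(intercept = -1e9, pitch = 0, amplitude = 0, age = 0),
      adult = c(intercept = -1e9, pitch = 0, amplitude = 0, age = 0)),
    nonspeech_infant_rate = 2,
    pitch_missing_prob = 0)
}

# null spec: genuine contingency structure (responses occur) but no planted
# effects -- scales 1, zero acoustic/age response coefficients
null_spec <- function(intercept = -1.2) {
  process_spec(
    post_response_interval_scale = 1,
    post_response_acoustic_scale = 1,
    response_logit_coefs = list(
      infant = c(intercept = intercept, pitch = 0, amplitude = 0, age = 0),
      adult = c(intercept = intercept, pitch = 0, amplitude = 0, age = 0)),
    nonspeech_infant_rate = 2,
    pitch_missing_prob = 0)
}
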