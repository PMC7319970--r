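# Response coding and step construction: rule-level checks, the
# hand-enumerated fixture, and equivalence with the exhaustive-scan coder.

simple_events <- function(lab, on, off) {
  n <- length(lab)
  data.frame(infant_id = "x", age_days = 100, subrecording_id = 0L,
             speaker_label = lab, onset_s = on, offset_s = off,
             mean_pitch_hz = 200, mean_amplitude_db = 60,
             pitch_z = 0, amp_z = 0, stringsAsFactors = FALSE)
}

test_that("single coding rules behave at their boundaries", {
  # adult answered by a CHNSP onset 0.5 s later -> Y
  ev <- simple_events(c("FAN", "CHNSP"), c(9.0, 10.5), c(10.0, 11.0))
  expect_identical(code_responses(ev)$response_code, c("Y", "N"))
  # two adult onsets 0.6 s apart, no infant between -> first is NA
  ev <- simple_events(c("FAN", "MAN"), c(9.0, 10.6), c(10.0, 11.2))
  expect_identical(code_responses(ev)$response_code[1], "NA")
  # response window exceeded (adult onset 1.2 s after infant offset) -> N
  ev <- simple_events(c("CHNSP", "FAN"), c(3.0, 5.2), c(4.0, 6.0))
  expect_identical(code_responses(ev)$response_code[1], "N")
  # onset exactly at offset + window counts as a response (half-open window)
  ev <- simple_events(c("CHNSP", "FAN"), c(3.0, 5.0), c(4.0, 6.0))
  expect_identical(code_responses(ev)$response_code[1], "Y")
  # an intervening same-side vocalisation blocks the response
  ev <- simple_events(c("CHNSP", "CHN_NSP", "FAN"), c(3.0, 4.2, 4.6), c(4.0, 4.5, 5.0))
  expect_identical(code_responses(ev)$response_code[1], "NA")
})

test_that("the 12-event fixture is coded and stepped exactly as enumerated", {
  ev <- standardise_acoustics(list(toy = toy_events()))$toy
  coded <- code_responses(ev)
  expect_identical(coded$response_code, toy_expected_codes())

  steps <- rbind(build_steps(coded, "infant"), build_steps(coded, "adult"))
  exp <- toy_expected_steps()
  expect_identical(nrow(steps), nrow(exp))
  expect_identical(steps$speaker_type, exp$speaker_type)
  expect_identical(steps$subrecording_id, exp$subrecording_id)
  expect_identical(steps$split_class, exp$split_class)
  expect_identical(steps$in_split_analysis, exp$in_split_analysis)
  expect_equal(steps$interval_s, exp$interval_s, tolerance = 1e-12)
  expect_equal(steps$d_pitch, exp$d_pitch, tolerance = 1e-9)
  expect_equal(steps$d_amp, exp$d_amp, tolerance = 1e-9)
  expect_equal(steps$s_2d, exp$s_2d, tolerance = 1e-9)

  # the "ge" retention convention flips only the interval == 1 s step
  ge <- build_steps(coded, "infant", interval_filter = "ge")
  expect_identical(ge$in_split_analysis, c(TRUE, TRUE, TRUE, TRUE))
})

test_that("fast coder matches the exhaustive-scan oracle across random sequences", {
  for (w in c(0.5, 1.0, 2.0)) {
    expect_identical(
      validate_response_coding(n_sequences = 60, n_events = 150,
                               window_s = w, seed = 1000 * w),
      0L, label = sprintf("window %.1f s", w))
  }
})

test_that("coding is invariant to OTHER events and steps respect stream counts", {
  ev <- simulate_random_events(300, seed = 11)
  base <- code_responses(ev)
  # inject OTHER events midway between existing ones (never overlapping)
  gaps <- which(ev$onset_s[-1] - ev$offset_s[-nrow(ev)] > 0.4 &
                  ev$subrecording_id[-1] == ev$subrecording_id[-nrow(ev)])
  ins <- ev[gaps, ]
  ins$speaker_label <- "OTHER"
  ins$onset_s <- ev$offset_s[gaps] + 0.1
  ins$offset_s <- ins$onset_s + 0.2
  aug <- rbind(ev, ins)
  aug <- aug[order(aug$onset_s), ]
  withother <- code_responses(aug)
  merged <- withother[withother$speaker_label != "OTHER", ]
  expect_identical(merged$response_code,
                   base$response_code[base$speaker_label != "OTHER"])

  # per-stream step count is n_events - 1 within each subrecording
  st <- build_steps(base, "adult")
  for (sub in unique(ev$subrecording_id)) {
    n_ad <- sum(ev$speaker_label %in% c("FAN", "MAN") & ev$subrecording_id == sub)
    expect_identical(sum(st$subrecording_id == sub), max(n_ad - 1L, 0L))
  }
  # WR class if and only if the first event was coded Y
  stI <- build_steps(base, "infant")
  first_codes <- base$response_code[stI$first_index]
  expect_identical(stI$split_class == "WR", first_codes == "Y")
})

test_that("degenerate inputs behave per contract", {
  ev <- simple_events("CHNSP", 1, 2)
  coded <- code_responses(ev)
  expect_identical(nrow(build_steps(coded, "infant")), 0L)
  expect_identical(nrow(build_steps(coded, "adult")), 0L)
  # unordered events are rejected
  bad <- simple_events(c("CHNSP", "FAN"), c(5, 1), c(6, 2))
  expect_error(code_responses(bad), "strictly increasing")
  # steps require coding first
  expect_error(build_steps(ev, "infant"), "code_responses")
})
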