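# Synthetic generator: determinism, timeline invariants, planted-structure
# recoverability and null calibration.

test_that("identical seeds give byte-identical recordings and cohorts", {
  sp <- process_spec()
  a <- generate_recording(sp, "i1", 180, 1800, seed = 9)
  b <- generate_recording(sp, "i1", 180, 1800, seed = 9)
  expect_identical(a, b)
  ch <- cohort_spec(n_infants = 2, ages_days = c(92, 184),
                    recording_length_s = 900, master_seed = 5)
  c1 <- generate_cohort(ch, sp)
  c2 <- generate_cohort(ch, sp)
  expect_identical(c1, c2)
})

test_that("cohort cardinality, seed derivation and duplicate detection", {
  ch <- cohort_spec(n_infants = 15, ages_days = c(92, 184, 276, 548),
                    recording_length_s = 120, master_seed = 2)
  sp <- quiet_spec()
  co <- generate_cohort(ch, sp)
  expect_length(co$recordings, 60)
  expect_identical(length(unique(co$truth$recording)), 60L)
  # per-recording seeds are independent of cohort composition
  ch2 <- cohort_spec(n_infants = 2, ages_days = c(92, 184),
                     recording_length_s = 120, master_seed = 2)
  co2 <- generate_cohort(ch2, sp)
  expect_identical(co$recordings[["inf01_092"]], co2$recordings[["inf01_092"]])
  expect_error(cohort_spec(ages_days = c(92, 92)), "duplicate")
  expect_error(cohort_spec(ages_days = c(10, 92)), "within")
  expect_error(cohort_spec(recording_length_s = 17 * 3600), "16 hours")
})

test_that("events never overlap, onsets increase, steps never span subrecordings", {
  sp <- process_spec()
  for (seed in 1:5) {
    rec <- generate_recording(sp, "i1", 276, 3600, seed = seed)
    expect_true(all(rec$offset_s > rec$onset_s))
    expect_true(all(diff(rec$onset_s) > 0))
    for (sub in unique(rec$subrecording_id)) {
      evs <- rec[rec$subrecording_id == sub, ]
      if (nrow(evs) > 1) {
        expect_true(all(evs$onset_s[-1] >= evs$offset_s[-nrow(evs)]))
      }
    }
  }
})

test_that("zero response probability yields no planted Y codes in sparse streams", {
  # sparse quiet spec: mean infant interval e^3 ~ 20 s, no adults -> no
  # chance collisions, and the coder must find nothing to call a response
  sp <- quiet_spec(infant_family = list(family = "lognormal", meanlog = 3, sdlog = 0.3))
  rec <- generate_recording(sp, "i1", 180, 3600, seed = 4)
  coded <- code_responses(split_subrecordings(rec))
  expect_false(any(coded$response_code == "Y", na.rm = TRUE))
})

test_that("planted lognormal intervals are recovered by the MLE fitter", {
  sp <- quiet_spec(infant_family = list(family = "lognormal", meanlog = 1.0, sdlog = 0.8))
  rec <- generate_recording(sp, "i1", 180, recording_length_s = 16 * 3600,
                            seed = 31, max_events = 25000)
  rec <- split_subrecordings(rec)
  expect_gt(nrow(rec), 5000)
  iv <- rec$onset_s[-1] - rec$offset_s[-nrow(rec)]
  f <- fit_mle(iv, "lognormal")
  expect_lt(abs(f$params[["meanlog"]] - 1.0), 0.05)
  expect_lt(abs(f$params[["sdlog"]] - 0.8), 0.05)
})

test_that("a planted post-response interval scale shortens WR intervals", {
  sp <- process_spec(post_response_interval_scale = 0.5,
                     interval_family = list(
                       infant = list(family = "lognormal", meanlog = 2.0, sdlog = 1.0),
                       adult = list(family = "pareto", xmin = 0.5, alpha = 1.3)))
  hits <- 0L
  for (k in 1:20) {
    rec <- generate_recording(sp, "i1", 180, 5400, seed = 300 + k)
    coded <- code_responses(standardise_acoustics(rec))
    st <- build_steps(coded, "infant")
    wr <- st$interval_s[st$split_class == "WR" & st$in_split_analysis]
    wor <- st$interval_s[st$split_class == "WOR" & st$in_split_analysis]
    if (length(wr) >= 5 && length(wor) >= 5 && median(wr) < median(wor)) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("with no planted effects WR and WOR step sizes are KS-indistinguishable", {
  sp <- null_spec()
  pvals <- c()
  k <- 0
  while (length(pvals) < 100 && k < 200) {
    k <- k + 1
    rec <- generate_recording(sp, "i1", 180, 2700, seed = 5000 + k)
    coded <- code_responses(standardise_acoustics(rec))
    st <- build_steps(coded, "infant")
    wr <- st$s_2d[st$split_class == "WR" & st$in_split_analysis]
    wor <- st$s_2d[st$split_class == "WOR" & st$in_split_analysis]
    if (length(wr) >= 5 && length(wor) >= 5) {
      pvals <- c(pvals, ks_two_sample(wr, wor)$p)
    }
  }
  expect_length(pvals, 100)
  expect_gte(sum(pvals >= 0.01), 97)
})

test_that("planted truth serialises and reads back", {
  ch <- cohort_spec(n_infants = 2, ages_days = c(92, 184),
                    recording_length_s = 1800, master_seed = 3)
  co <- generate_cohort(ch, process_spec())
  path <- withr::local_tempfile(fileext = ".txt")
  write_planted_truth(co$truth, path)
  back <- read_planted_truth(path)
  expect_identical(back$recording, co$truth$recording)
  expect_identical(back$parameter, co$truth$parameter)
  expect_identical(back$value, co$truth$value)
})

test_that("invalid process specifications are rejected", {
  expect_error(process_spec(post_response_interval_scale = 0), "positive")
  expect_error(process_spec(interval_family = list(
    infant = list(family = "pareto", xmin = 1, alpha = 0.9),
    adult = list(family = "pareto", xmin = 0.5, alpha = 1.2))), "alpha")
  expect_error(process_spec(interval_family = list(
    infant = list(family = "normal", mean = 1, sd = 1),
    adult = list(family = "pareto", xmin = 0.5, alpha = 1.2))), "normal")
  # infeasible: expected interval far beyond the recording
  sp <- quiet_spec(infant_family = list(family = "lognormal", meanlog = 12, sdlog = 0.1),
                   adult_family = list(family = "lognormal", meanlog = 12, sdlog = 0.1))
  expect_error(generate_recording(sp, "i1", 180, 60, seed = 1), "infeasible")
})
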