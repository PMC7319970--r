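# Segment-table I/O, preprocessing and standardisation.

test_that("segment tables round-trip exactly through the CSV dialect", {
  ev <- toy_events()
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(ev, path)
  back <- read_segments(path)
  for (nm in c("onset_s", "offset_s", "mean_pitch_hz", "mean_amplitude_db")) {
    expect_identical(back[[nm]], ev[[nm]], label = nm)
  }
  expect_identical(back$speaker_label, ev$speaker_label)
  expect_identical(back$subrecording_id, ev$subrecording_id)
  expect_identical(sample_size(back), 11L)
})

test_that("empty tables and unknown labels are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(toy_events()[0, ], path)
  rec <- read_segments(path)
  expect_identical(nrow(rec), 0L)
  expect_identical(sample_size(rec), 0L)

  ev <- toy_events()
  ev$speaker_label[2] <- "CXN" # near other-child: not an analysed label
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_segments(ev, path2)
  expect_identical(read_segments(path2)$speaker_label[2], "OTHER")
})

test_that("timeline violations raise errors naming the line", {
  ev <- toy_events()
  ev$offset_s[2] <- ev$onset_s[2] - 0.1
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(ev, path)
  expect_error(read_segments(path), "line 3") # line 2 of data, 3 of file

  ev2 <- toy_events()
  ev2$offset_s[1] <- 2.0 # overlaps event 2 (onset 1.8)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_segments(ev2, path2)
  expect_error(read_segments(path2), "overlap")
})

test_that("unpitched events are removed and counted before step construction", {
  ev <- simulate_random_events(10, seed = 3)
  ev$pitch_missing <- c(FALSE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 5))
  kept <- drop_unpitched(ev)
  expect_identical(nrow(kept), 8L)
  expect_identical(attr(kept, "n_unpitched"), 2L)
  # consecutive-step structure is recomputed over survivors: enumerate by hand
  ev$speaker_label <- rep("CHNSP", 10)
  ev$subrecording_id <- 0L
  kept <- drop_unpitched(ev)
  kept$pitch_z <- seq_len(8); kept$amp_z <- 0
  kept <- code_responses(kept)
  st <- build_steps(kept, "infant")
  expect_identical(nrow(st), 7L)
  expect_equal(st$interval_s, kept$onset_s[-1] - kept$offset_s[-8])
})

test_that("standardisation uses pooled population statistics of coded speakers", {
  recs <- standardise_acoustics(list(a = toy_events()))
  ev <- recs$a
  pool <- ev$speaker_label %in% c("CHNSP", "FAN", "MAN")
  expect_equal(mean(ev$pitch_z[pool]), 0, tolerance = 1e-12)
  expect_equal(popsd(ev$pitch_z[pool]), 1, tolerance = 1e-12)
  expect_equal(mean(ev$amp_z[pool]), 0, tolerance = 1e-12)
  expect_equal(popsd(ev$amp_z[pool]), 1, tolerance = 1e-12)
  # the CHN_NSP event is scored against the pooled stats, not the pool
  expect_equal(ev$pitch_z[4], (5.5 - 5.5) / sqrt(1.38 / 11), tolerance = 1e-9)
  # two-point recording: population-SD convention gives z = +/- 1
  two <- toy_events()[c(1, 2), ]
  z <- standardise_acoustics(list(r = two))$r$pitch_z
  expect_equal(sort(z), c(-1, 1), tolerance = 1e-12)
})

test_that("zero acoustic variance is a standardisation error", {
  ev <- toy_events()
  ev$mean_amplitude_db <- 60
  expect_error(standardise_acoustics(list(a = ev)), "zero variance")
})

test_that("subrecording assignment respects pauses and rejects overlaps", {
  ev <- toy_events()
  ev$subrecording_id <- NA_integer_
  out <- split_subrecordings(ev, pauses = data.frame(start_s = 20, end_s = 80))
  expect_identical(out$subrecording_id, c(rep(0L, 9), rep(1L, 3)))
  expect_error(
    split_subrecordings(ev, pauses = data.frame(start_s = 1.2, end_s = 1.4)),
    "overlaps event")
  # no pauses: single subrecording
  ev$subrecording_id <- NULL
  expect_true(all(split_subrecordings(ev)$subrecording_id == 0L))
})
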