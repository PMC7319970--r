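#!/usr/bin/env Rscript
# Stage 1: simulate a cohort of day-long, speaker-labelled vocalisation
# tables with known (planted) structure and write them as segment CSVs.
#
# The process plants the two effects the downstream stages should recover:
#   * post-response interval scale 0.7 -- a vocaliser's next interval is
#     shorter right after receiving a response (area-restricted search);
#   * a positive age trend (+0.15 per 100 days, log scale) in acoustic
#     step size.
# Recording length is 2 h per recording here so the whole analysis run
# stays in the minutes range; see the methods vignette for the scaling
# rationale.

library(vocalforage)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- process_spec(
  post_response_interval_scale = 0.7,
  age_effects = list(infant_interval = 0, adult_interval = 0, acoustic_step = 0.15))
cohort <- cohort_spec(n_infants = 8, ages_days = c(92, 184, 276, 548),
                      recording_length_s = 2 * 3600, master_seed = 20260923L)

cat("Simulating", cohort$n_infants, "infants x", length(cohort$ages_days),
    "ages (", cohort$recording_length_s / 3600, "h recordings) ...\n")
sim <- generate_cohort(cohort, spec)

manifest <- data.frame(path = character(), infant_id = character(),
                       age_days = numeric())
for (key in names(sim$recordings)) {
  f <- paste0(key, ".csv")
  write_segments(sim$recordings[[key]], file.path(out_dir, f))
  rec <- sim$recordings[[key]]
  manifest <- rbind(manifest, data.frame(path = f, infant_id = rec$infant_id[1],
                                         age_days = rec$age_days[1]))
}
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
write_planted_truth(sim$truth, file.path(out_dir, "planted_truth.txt"))

n_ev <- vapply(sim$recordings, nrow, 0L)
cat(sprintf("Wrote %d recordings (%d events total, median %d per recording)\n",
            length(sim$recordings), sum(n_ev), as.integer(median(n_ev))))
cat("Planted truth serialised to", file.path(out_dir, "planted_truth.txt"), "\n")
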