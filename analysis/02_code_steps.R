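#!/usr/bin/env Rscript
# Stage 2: read the simulated segment tables back through the I/O layer,
# drop unpitched utterances, z-score the acoustic space over the whole
# cohort, code responses under the 1-s contingency scheme, and build the
# same-speaker-type step tables.

library(vocalforage)

recordings <- read_cohort("results/data/manifest.csv")
cat("Loaded", length(recordings), "recordings\n")

coded <- prepare_cohort(recordings, window_s = 1.0)
codes <- unlist(lapply(coded, function(ev) ev$response_code))
cat("Response codes:", paste(sprintf("%s=%d", names(table(codes)), table(codes)),
                             collapse = "  "), "\n")

steps <- cohort_steps(coded, interval_filter = "gt", filter_s = 1.0)
cat(sprintf("Built %d steps (%d infant, %d adult); %.1f%% retained for split analyses\n",
            nrow(steps), sum(steps$speaker_type == "infant"),
            sum(steps$speaker_type == "adult"),
            100 * mean(steps$in_split_analysis)))

annotated <- do.call(rbind, lapply(names(coded), function(k) {
  ev <- coded[[k]]; ev$recording <- k; ev
}))
write.csv(annotated, "results/annotated_events.csv", row.names = FALSE)
write.csv(steps, "results/steps.csv", row.names = FALSE)
sizes <- cohort_sample_sizes(coded)
write.csv(sizes, "results/sample_sizes.csv", row.names = FALSE)
cat("Wrote results/annotated_events.csv, results/steps.csv, results/sample_sizes.csv\n")
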