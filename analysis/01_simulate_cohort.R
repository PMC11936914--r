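#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a 60 ADHD + 60 control cohort (plus 6 self-suspected
# participants who will be excluded from group models) over the full task:
# 30 personality words, 24 rated emotion words, and the 50-word daily-life
# inventory. Writes the four raw artefacts in the pipeline's on-disk
# dialects, with generator ground truth segregated under truth/.

suppressPackageStartupMessages(library(stroopwoi))

out <- "results/data"
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_adhd = 60, n_control = 60, n_excluded = 6,
                     seed = 20251)
cohort <- generate_cohort(cfg)

write_trial_log(cohort$trials, file.path(out, "trials.csv"))
write_word_list(cohort$word_list, file.path(out, "word_list.json"))
write_participants(cohort$participants, file.path(out, "participants.csv"),
                   cohort$ratings, file.path(out, "ratings.csv"))
utils::write.csv(cohort$truth$planted,
                 file.path(out, "truth", "planted_issues.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$truth$expected,
                 file.path(out, "truth", "expected_latencies.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$truth$contamination,
                 file.path(out, "truth", "contamination.csv"),
                 row.names = FALSE)

message(sprintf(
  "simulated %d participants x %d words -> %d trials (%d contaminated)",
  nrow(cohort$participants), nrow(cohort$word_list), nrow(cohort$trials),
  nrow(cohort$truth$contamination)))
message("artefacts under ", out)
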