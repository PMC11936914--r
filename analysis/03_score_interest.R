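#!/usr/bin/env Rscript
# Stage 3: words-of-interest scoring.
#
# Flags each participant's words of interest at the working cut-off
# z > 1.5, writes one ranked JSON report per participant (including the
# excluded self-suspected participants — reports are individual-level and
# remain producible for them), and the cohort-level percentage table the
# group models consume.

suppressPackageStartupMessages(library(stroopwoi))

data_dir <- "results/data"
out <- "results/scored"
dir.create(file.path(out, "profiles"), recursive = TRUE, showWarnings = FALSE)

wl <- read_word_list(file.path(data_dir, "word_list.json"))
meta <- read_participants(file.path(data_dir, "participants.csv"))$participants
z_scores <- tibble::as_tibble(
  utils::read.csv("results/preprocessed/z_scores.csv"))

config <- scoring_config(z_threshold = 1.5)
for (pid in meta$participant_id) {
  prof <- build_interest_profile(pid, z_scores, wl, config)
  write_interest_report(prof,
                        file.path(out, "profiles", paste0(pid, ".json")),
                        provenance = list(source = "results/data",
                                          generator_seed = 20251,
                                          z_threshold = 1.5))
}

kept <- meta$participant_id[meta$diagnosis != "excluded_suspected"]
tab <- cohort_interest_table(z_scores[z_scores$participant_id %in% kept, ],
                             wl, config)
utils::write.csv(tab$percentages, file.path(out, "percentages.csv"),
                 row.names = FALSE)
utils::write.csv(tab$issue_counts, file.path(out, "issue_counts.csv"),
                 row.names = FALSE)

message(sprintf(
  "wrote %d profiles; mean daily-life issues per analysed participant: %.2f (sd %.2f) out of 50",
  nrow(meta), mean(tab$issue_counts$n_issues),
  stats::sd(tab$issue_counts$n_issues)))
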