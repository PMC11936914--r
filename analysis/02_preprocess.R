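#!/usr/bin/env Rscript
# Stage 2: latency preprocessing.
#
# Reads the simulated raw artefacts back from disk (exercising the full
# validation path), applies the fixed preprocessing order — fast-trial
# filter (< 100 ms), red/blue averaging, slow-word filter (> 2,000 ms),
# within-participant z-scoring per task section — and writes the word-mean
# and z-score tables plus the removal audit.

suppressPackageStartupMessages(library(stroopwoi))

data_dir <- "results/data"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wl <- read_word_list(file.path(data_dir, "word_list.json"))
trials <- read_trial_log(file.path(data_dir, "trials.csv"), wl)
pre <- preprocess_trials(trials, wl)

utils::write.csv(pre$word_latencies, file.path(out, "word_latencies.csv"),
                 row.names = FALSE)
utils::write.csv(pre$z_scores, file.path(out, "z_scores.csv"),
                 row.names = FALSE)
utils::write.csv(pre$audit, file.path(out, "audit.csv"), row.names = FALSE)

print(pre$audit)
message(sprintf(
  "removed %d fast trial(s) and %d slow word mean(s); %d word means kept",
  nrow(pre$dropped_fast), nrow(pre$dropped_slow), nrow(pre$word_latencies)))
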