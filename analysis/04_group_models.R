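#!/usr/bin/env Rscript
# Stage 4: the three group-level models.
#
# 1. Two-way diagnosis x category ANOVA on personality-section percentages,
#    swept over the four conventional cut-offs (0.5, 1.0, 1.5, 2.0).
# 2. Moderated regression of emotion-word latency on the participant's own
#    valence rating, diagnosis, and their interaction.
# 3. Logistic diagnostic models from the daily-life percentages, without
#    (model 1) and with (model 2) the screener total.
# Emits a JSON bundle plus a plain-text summary.

suppressPackageStartupMessages(library(stroopwoi))

data_dir <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wl <- read_word_list(file.path(data_dir, "word_list.json"))
trials <- read_trial_log(file.path(data_dir, "trials.csv"), wl)
md <- read_participants(file.path(data_dir, "participants.csv"),
                        file.path(data_dir, "ratings.csv"))

res <- run_stroop_pipeline(trials, wl, md$participants, md$ratings,
                           out_dir = out)

summary_path <- file.path(out, "summary.txt")
con <- file(summary_path, open = "w")
sink(con)
cat("=== ANOVA sweep: personality-trait words of interest ===\n")
for (a in res$anova) print(a)
cat("\n=== Moderated regression: emotion-word latency ~ valence x diagnosis ===\n")
print(res$regression)
cat("\n=== Logistic diagnosis models from daily-life percentages ===\n")
cat("-- model 1 (percentages only)\n")
print(res$logistic$model1)
cat("-- model 2 (percentages + screener)\n")
print(res$logistic$model2)
sink()
close(con)

writeLines(readLines(summary_path))
message("bundle written to ", file.path(out, "group_analysis.json"))
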