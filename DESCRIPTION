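Package: stroopwoi
Title: Words-of-Interest Analysis for Modified Emotional Stroop Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for analysing response latencies from modified
    (emotional) Stroop tasks in which personally salient words capture
    attention and slow colour naming. Implements latency preprocessing
    (fast-trial and slow-word outlier filters, red/blue colour averaging,
    within-participant z-standardisation), thresholded "words of interest"
    scoring with per-category percentages, and three group-level models:
    a two-way diagnosis-by-category ANOVA with partial eta squared, a
    moderated regression of latency on word valence with a
    valence-by-diagnosis interaction, and a logistic diagnostic classifier
    with sensitivity and specificity. A synthetic cohort generator with
    ex-Gaussian reaction-time noise, planted issue words and extreme-latency
    contamination makes every stage testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
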