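# Brute-force oracles, written independently of the implementation paths
# they check: explicit loops and textbook formulas only.

oracle_zscore <- function(latencies, scope = "per_section") {
  out <- latencies
  out$z <- NA_real_
  key <- if (scope == "per_section") {
    paste(latencies$participant_id, latencies$section)
  } else {
    latencies$participant_id
  }
  for (k in unique(key)) {
    idx <- which(key == k)
    x <- latencies$mean_latency_ms[idx]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    out$z[idx] <- (x - m) / s
  }
  out
}

oracle_flag <- function(z_scores, threshold) {
  keep <- z_scores[z_scores$z > threshold, , drop = FALSE]
  keep <- keep[order(-keep$z, keep$word), , drop = FALSE]
  keep[, c("word", "section", "category", "z")]
}

oracle_percentage <- function(flagged, word_list, section, category) {
  denom <- 0
  num <- 0
  for (i in seq_len(nrow(word_list))) {
    if (word_list$section[i] == section && word_list$category[i] == category)
      denom <- denom + 1
  }
  for (i in seq_len(nrow(flagged))) {
    if (flagged$section[i] == section && flagged$category[i] == category)
      num <- num + 1
  }
  100 * num / denom
}

# Balanced two-way ANOVA (factors A, B; equal cell sizes) from raw sums of
# squares; returns per-term df, F and partial eta squared.
oracle_anova_balanced <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  a_lv <- unique(A); b_lv <- unique(B)
  a <- length(a_lv); b <- length(b_lv)
  n_cell <- length(y) / (a * b)
  stopifnot(n_cell == round(n_cell))
  grand <- mean(y)
  ss_a <- 0
  for (ai in a_lv) ss_a <- ss_a + n_cell * b * (mean(y[A == ai]) - grand)^2
  ss_b <- 0
  for (bi in b_lv) ss_b <- ss_b + n_cell * a * (mean(y[B == bi]) - grand)^2
  ss_ab <- 0; ss_e <- 0
  for (ai in a_lv) for (bi in b_lv) {
    cell <- y[A == ai & B == bi]
    ss_ab <- ss_ab +
      n_cell * (mean(cell) - mean(y[A == ai]) - mean(y[B == bi]) + grand)^2
    ss_e <- ss_e + sum((cell - mean(cell))^2)
  }
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_e <- a * b * (n_cell - 1)
  list(
    F = c(diagnosis = (ss_a / df_a) / (ss_e / df_e),
          category = (ss_b / df_b) / (ss_e / df_e),
          interaction = (ss_ab / df_ab) / (ss_e / df_e)),
    df = c(diagnosis = df_a, category = df_b, interaction = df_ab),
    df_error = df_e,
    partial_eta_sq = c(diagnosis = ss_a / (ss_a + ss_e),
                       category = ss_b / (ss_b + ss_e),
                       interaction = ss_ab / (ss_ab + ss_e)),
    r_squared = (ss_a + ss_b + ss_ab) / (ss_a + ss_b + ss_ab + ss_e))
}
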