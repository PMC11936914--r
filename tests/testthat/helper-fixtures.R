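# Small in-code fixtures shared across the suite.

tiny_word_list <- function() {
  tibble::tibble(
    text = c("restless", "calm_trait", "lamp",
             "joy", "table", "grief",
             "deadline", "meeting", "cloud"),
    section = c(rep("personality", 3), rep("emotion", 3), rep("work", 3)),
    category = c("related", "unrelated", "distraction",
                 "positive", "neutral", "negative",
                 "related", "unrelated", "distraction"),
    norm_valence = c(NA, NA, 4.0, 6.5, 4.0, 1.5, NA, NA, 4.2))
}

# Build a trial tibble giving each (word, colour) the stated latency.
make_trials <- function(word_list, participant_id = "P1",
                        latency_red = 500, latency_blue = 500) {
  n <- nrow(word_list)
  lat_red <- rep_len(latency_red, n)
  lat_blue <- rep_len(latency_blue, n)
  tibble::tibble(
    participant_id = participant_id,
    section = rep(word_list$section, each = 2),
    word = rep(word_list$text, each = 2),
    ink_color = rep(c("red", "blue"), times = n),
    latency_ms = as.vector(rbind(lat_red, lat_blue)),
    trial_index = seq_len(2 * n) - 1L)
}

# Word-latency table (post colour averaging) straight from given means.
make_word_latencies <- function(word_list, participant_id = "P1",
                                mean_latency_ms) {
  tibble::tibble(
    participant_id = participant_id,
    word = word_list$text,
    section = word_list$section,
    category = word_list$category,
    mean_latency_ms = mean_latency_ms,
    n_colors_used = 2L)
}

# z-score table from explicit z values.
make_z_scores <- function(word_list, participant_id = "P1", z) {
  tibble::tibble(
    participant_id = participant_id,
    word = word_list$text,
    section = word_list$section,
    category = word_list$category,
    z = z)
}
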