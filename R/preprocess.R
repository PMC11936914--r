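## Latency preprocessing, in fixed, auditable order:
##   1. fast-trial filter   (raw trials with latency < min_ms dropped)
##   2. colour averaging    ((lat_red + lat_blue) / 2 per participant-word)
##   3. slow-word filter    (word means > max_ms removed)
##   4. within-participant z-standardisation
## Boundary convention is strict on both rules ("smaller than" / "larger
## than"): a 100 ms trial and a 2,000 ms word mean are both kept.

#' Drop implausibly fast trials
#'
#' Removes raw trials whose latency is strictly smaller than `min_ms`
#' (anticipations / accidental key presses). Dropped trials are returned for
#' audit, never silently discarded.
#'
#' @param trials Trial tibble (see [validate_trials()] for the shape).
#' @param min_ms Strict lower bound in milliseconds (default 100).
#' @return `list(kept, dropped)`, a disjoint partition of the input rows.
#' @export
filter_fast_trials <- function(trials, min_ms = 100) {
  if (!is.numeric(min_ms) || length(min_ms) != 1 || min_ms <= 0) {
    stop_domain("min_ms must be a single positive number")
  }
  keep <- trials$latency_ms >= min_ms
  list(kept = trials[keep, , drop = FALSE],
       dropped = trials[!keep, , drop = FALSE])
}

#' Average red and blue presentations into one latency per word
#'
#' Each word is shown once in red and once in blue; the per-word latency is
#' the mean of the two. When one colour was removed by the fast-trial
#' filter, the surviving observation is used alone (`n_colors_used = 1`) so
#' the word stays in the issue inventory; words with no surviving trial are
#' absent from the output. Duplicate colours for a word are an error.
#'
#' @param trials Fast-filtered trial tibble for one or more participants.
#' @param word_list Validated word list (supplies each word's category).
#' @return Tibble with one row per (participant, word):
#'   `participant_id`, `word`, `section`, `category`, `mean_latency_ms`,
#'   `n_colors_used`.
#' @export
average_color_latencies <- function(trials, word_list) {
  wl <- validate_word_list(word_list)
  dup <- duplicated(paste(trials$participant_id, trials$section, trials$word,
                          trials$ink_color, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1]
    stop_validation(sprintf(
      "duplicate %s trial for participant %s, word '%s'",
      trials$ink_color[i], trials$participant_id[i], trials$word[i]))
  }
  out <- trials |>
    dplyr::group_by(.data$participant_id, .data$section, .data$word) |>
    dplyr::summarise(mean_latency_ms = mean(.data$latency_ms),
                     n_colors_used = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(wl[, c("text", "section", "category")],
                     by = c(word = "text", section = "section"))
  if (anyNA(out$category)) {
    stop_validation("trial word missing from word list")
  }
  out[, c("participant_id", "word", "section", "category",
          "mean_latency_ms", "n_colors_used")]
}

#' Remove extreme slow word means
#'
#' Removes per-word mean latencies strictly larger than `max_ms`
#' (attentional lapses, interruptions). Applied to word means, after colour
#' averaging; removed rows are returned for audit.
#'
#' @param latencies Word-latency tibble from [average_color_latencies()].
#' @param max_ms Strict upper bound in milliseconds (default 2000).
#' @return `list(kept, dropped)`, a disjoint partition of the input rows.
#' @export
filter_slow_word_latencies <- function(latencies, max_ms = 2000) {
  if (!is.numeric(max_ms) || length(max_ms) != 1 || max_ms <= 0) {
    stop_domain("max_ms must be a single positive number")
  }
  keep <- latencies$mean_latency_ms <= max_ms
  list(kept = latencies[keep, , drop = FALSE],
       dropped = latencies[!keep, , drop = FALSE])
}

#' Standardise word latencies within participant
#'
#' Mean response latency varies a lot between participants, so word means
#' are z-scored within participant before thresholding: z = (x - m) / s with
#' m and s the participant's scope-group sample mean and sample SD (n - 1
#' denominator). The default scope standardises each task section (round)
#' separately, since rounds differ in difficulty and fatigue;
#' `"all_sections"` pools a participant's words for sensitivity analysis.
#'
#' @param latencies Word-latency tibble (post filters).
#' @param scope `"per_section"` (default) or `"all_sections"`.
#' @param min_group Minimum words per standardisation group (default 3);
#'   smaller groups are an error, as is zero variance.
#' @return Tibble `participant_id`, `word`, `section`, `category`, `z`;
#'   within every scope-group, mean(z) = 0 and SD(z) = 1 to 1e-9.
#' @export
zscore_within_participant <- function(latencies,
                                      scope = c("per_section", "all_sections"),
                                      min_group = 3) {
  scope <- match.arg(scope)
  grp <- if (scope == "per_section") {
    paste(latencies$participant_id, latencies$section, sep = "\r")
  } else {
    latencies$participant_id
  }
  n <- table(grp)
  if (any(n < min_group)) {
    bad <- names(n)[which(n < min_group)[1]]
    stop_domain(sprintf(
      "standardisation group '%s' has fewer than %d words",
      gsub("\r", " / ", bad), min_group))
  }
  s <- tapply(latencies$mean_latency_ms, grp, stats::sd)
  if (any(s == 0)) {
    bad <- names(s)[which(s == 0)[1]]
    stop_domain(sprintf(
      "zero latency variance for standardisation group '%s'",
      gsub("\r", " / ", bad)))
  }
  m <- tapply(latencies$mean_latency_ms, grp, mean)
  out <- latencies
  out$z <- as.vector((latencies$mean_latency_ms - m[grp]) / s[grp])
  out[, c("participant_id", "word", "section", "category", "z")]
}

#' Run the full preprocessing chain with an audit trail
#'
#' Applies, in order: fast-trial filter, colour averaging, slow-word filter,
#' within-participant z-scoring. The audit table records rows in/out/removed
#' at each stage so outlier removals are traceable.
#'
#' @param trials Validated trial tibble.
#' @param word_list Validated word list.
#' @inheritParams filter_fast_trials
#' @inheritParams filter_slow_word_latencies
#' @inheritParams zscore_within_participant
#' @return `list(word_latencies, z_scores, dropped_fast, dropped_slow,
#'   audit)`; `audit` is a tibble with columns `stage`, `n_in`, `n_out`,
#'   `n_removed` (units: trials for the fast filter, word means afterwards).
#' @export
preprocess_trials <- function(trials, word_list, min_ms = 100, max_ms = 2000,
                              scope = c("per_section", "all_sections"),
                              min_group = 3) {
  scope <- match.arg(scope)
  fast <- filter_fast_trials(trials, min_ms = min_ms)
  latencies <- average_color_latencies(fast$kept, word_list)
  slow <- filter_slow_word_latencies(latencies, max_ms = max_ms)
  z <- zscore_within_participant(slow$kept, scope = scope,
                                 min_group = min_group)
  audit <- tibble::tibble(
    stage = c("fast_trial_filter", "color_averaging",
              "slow_word_filter", "zscore"),
    n_in = c(nrow(trials), nrow(fast$kept), nrow(latencies), nrow(slow$kept)),
    n_out = c(nrow(fast$kept), nrow(latencies), nrow(slow$kept), nrow(z)),
    n_removed = c(nrow(fast$dropped), NA_integer_, nrow(slow$dropped), 0L))
  list(word_latencies = slow$kept, z_scores = z,
       dropped_fast = fast$dropped, dropped_slow = slow$dropped,
       audit = audit)
}
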