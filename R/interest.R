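## The bespoke statistic: "words of interest". A word is of interest for a
## participant when its standardised latency strictly exceeds a z cut-off;
## the per-category percentage divides the flagged count by the designed
## word-list size of that (section, category), so percentages stay
## comparable across participants regardless of outlier removals.

#' Scoring configuration for words of interest
#'
#' The cut-off is intentionally tunable (a therapist-set dial); analyses
#' are conventionally run over the cut-offs 0.5, 1.0, 1.5 and 2.0, with 1.5
#' as the working default for daily-life profiling (a reasonable number of
#' flagged words per participant).
#'
#' @param z_threshold Positive z cut-off (default 1.5); a word is flagged
#'   only when its z strictly exceeds it.
#' @param sections_in_scope Sections whose words are scored (default: all
#'   seven task sections).
#' @param headline_sections Sections whose flags count toward the headline
#'   "issues per participant" number (default: the five daily-life domains,
#'   i.e. out of the 50-word inventory).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(z_threshold = 1.5,
                           sections_in_scope = stroop_sections(),
                           headline_sections = daily_life_sections()) {
  if (!is.numeric(z_threshold) || length(z_threshold) != 1 ||
      !is.finite(z_threshold) || z_threshold <= 0) {
    stop_domain("z_threshold must be a single positive number")
  }
  bad <- setdiff(sections_in_scope, .SECTIONS)
  if (length(bad) > 0) {
    stop_domain(sprintf("unknown section(s) in scope: %s",
                        paste(bad, collapse = ", ")))
  }
  structure(list(z_threshold = z_threshold,
                 supported_thresholds = c(0.5, 1.0, 1.5, 2.0),
                 sections_in_scope = sections_in_scope,
                 headline_sections = headline_sections),
            class = "scoring_config")
}

#' Flag a participant's words of interest
#'
#' Returns the z-scored words whose z strictly exceeds the configured
#' cut-off, sorted z-descending; ties in z are broken by word text
#' (ascending) so reports are bit-for-bit reproducible. Input must belong
#' to a single participant.
#'
#' @param z_scores Tibble from [zscore_within_participant()], one
#'   participant.
#' @param config A [scoring_config()].
#' @return Tibble `word`, `section`, `category`, `z` (possibly empty).
#' @export
flag_words_of_interest <- function(z_scores, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  if (length(unique(z_scores$participant_id)) > 1) {
    stop_domain("flag_words_of_interest expects a single participant")
  }
  zs <- z_scores[z_scores$section %in% config$sections_in_scope, ,
                 drop = FALSE]
  flagged <- zs[zs$z > config$z_threshold, , drop = FALSE]
  flagged <- flagged[order(-flagged$z, flagged$word), , drop = FALSE]
  tibble::as_tibble(flagged[, c("word", "section", "category", "z")])
}

#' Percentage of words of interest in one (section, category)
#'
#' 100 x (flagged words in the cell) / (words the list assigns to the
#' cell). The denominator is the designed word list, not the post-filter
#' observed words: a word removed as a slow outlier still counts in the
#' denominator.
#'
#' @param flagged Flagged-word tibble from [flag_words_of_interest()].
#' @param word_list Validated word list.
#' @param section,category The cell to score.
#' @return A percentage in \[0, 100\].
#' @export
percentage_of_interest <- function(flagged, word_list, section, category) {
  wl <- validate_word_list(word_list)
  denom <- sum(wl$section == section & wl$category == category)
  if (denom == 0) {
    stop_domain(sprintf(
      "word list has no words in section '%s', category '%s'",
      section, category))
  }
  num <- sum(flagged$section == section & flagged$category == category)
  100 * num / denom
}

new_interest_profile <- function(participant_id, z_threshold, flagged_words,
                                 category_percentages) {
  headline <- flagged_words$section %in% daily_life_sections()
  structure(list(participant_id = participant_id,
                 z_threshold = z_threshold,
                 flagged_words = flagged_words,
                 category_percentages = category_percentages,
                 n_issues = sum(headline)),
            class = "interest_profile")
}

#' Build a participant's interest profile
#'
#' Bundles the participant's flagged words (ranked by z) with every
#' (section, category) percentage in scope. The headline `n_issues` counts
#' flagged words across the five daily-life domains only — the number of
#' issues a therapist would see out of the designed inventory; personality
#' and emotion flags are reported but kept separate.
#'
#' @param participant Either a participant id or a one-row metadata tibble.
#' @param z_scores z-scored latencies for that participant.
#' @param word_list Validated word list.
#' @param config A [scoring_config()].
#' @return An `interest_profile` object.
#' @export
build_interest_profile <- function(participant, z_scores, word_list,
                                   config = scoring_config()) {
  pid <- if (is.character(participant)) participant else {
    as.character(participant$participant_id[1])
  }
  zs <- z_scores[z_scores$participant_id == pid, , drop = FALSE]
  flagged <- flag_words_of_interest(zs, config)
  wl <- validate_word_list(word_list)
  cells <- dplyr::distinct(wl[wl$section %in% config$sections_in_scope,
                              c("section", "category")])
  cells$n_words <- vapply(seq_len(nrow(cells)), function(i) {
    sum(wl$section == cells$section[i] & wl$category == cells$category[i])
  }, numeric(1))
  cells$n_flagged <- vapply(seq_len(nrow(cells)), function(i) {
    sum(flagged$section == cells$section[i] &
          flagged$category == cells$category[i])
  }, numeric(1))
  cells$percentage <- vapply(seq_len(nrow(cells)), function(i) {
    percentage_of_interest(flagged, wl, cells$section[i], cells$category[i])
  }, numeric(1))
  new_interest_profile(pid, config$z_threshold, flagged,
                       tibble::as_tibble(cells))
}

#' @export
print.interest_profile <- function(x, ...) {
  cat(sprintf("Interest profile for %s (z > %.2f)\n", x$participant_id,
              x$z_threshold))
  cat(sprintf("  %d daily-life issue(s) flagged out of %d inventory words\n",
              x$n_issues,
              sum(x$category_percentages$n_words[
                x$category_percentages$section %in% daily_life_sections()])))
  if (nrow(x$flagged_words) > 0) {
    top <- utils::head(x$flagged_words, 10)
    cat("  top flagged words:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-28s %-13s z = %.2f\n", top$word[i], top$section[i],
                  top$z[i]))
    }
  }
  invisible(x)
}

#' Cohort-level words-of-interest table
#'
#' Computes, for every participant in `z_scores`, the percentage of words
#' of interest in every (section, category) cell plus the headline
#' daily-life issue count — the exact input shape the group-level models
#' consume.
#'
#' @param z_scores z-scored latencies for a cohort.
#' @param word_list Validated word list.
#' @param config A [scoring_config()].
#' @return `list(percentages, issue_counts)`: `percentages` is a tibble
#'   `participant_id`, `section`, `category`, `n_words`, `n_flagged`,
#'   `percentage`; `issue_counts` has `participant_id`, `n_issues`.
#' @export
cohort_interest_table <- function(z_scores, word_list,
                                  config = scoring_config()) {
  wl <- validate_word_list(word_list)
  ids <- unique(z_scores$participant_id)
  rows <- lapply(ids, function(pid) {
    prof <- build_interest_profile(pid, z_scores, wl, config)
    cp <- prof$category_percentages
    cp$participant_id <- pid
    list(perc = cp, issues = tibble::tibble(participant_id = pid,
                                            n_issues = prof$n_issues))
  })
  perc <- dplyr::bind_rows(lapply(rows, `[[`, "perc"))
  perc <- perc[, c("participant_id", "section", "category", "n_words",
                   "n_flagged", "percentage")]
  list(percentages = perc,
       issue_counts = dplyr::bind_rows(lapply(rows, `[[`, "issues")))
}
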