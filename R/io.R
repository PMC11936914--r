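## Readers/writers for the pipeline's plain-text artefacts: trial logs and
## participant metadata as CSV, word lists and per-participant reports as
## JSON. All validation is total: malformed rows raise classed errors
## (stroopwoi_validation_error) naming the offending row, never a silent drop.

.TRIAL_COLUMNS <- c("participant_id", "section", "word", "ink_color",
                    "latency_ms", "trial_index")

#' Validate a trial table against a word list
#'
#' Checks, row by row: known section; word present in the word list under
#' that section; ink colour red or blue; finite positive latency; and at
#' most one trial per (participant, word, ink colour) — each word is shown
#' once in red and once in blue per session.
#'
#' @param trials Data frame with columns `participant_id`, `section`,
#'   `word`, `ink_color`, `latency_ms`, `trial_index`.
#' @param word_list Validated word list (see [validate_word_list()]).
#' @return The validated trials as a tibble, word text normalised.
#' @export
validate_trials <- function(trials, word_list) {
  missing <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing) > 0) {
    stop_validation(sprintf("trial table is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  wl <- validate_word_list(word_list)
  tr <- tibble::as_tibble(trials)[, .TRIAL_COLUMNS]
  tr$participant_id <- as.character(tr$participant_id)
  tr$word <- normalize_word(as.character(tr$word))
  tr$section <- as.character(tr$section)
  tr$ink_color <- as.character(tr$ink_color)

  bad_row <- function(cond, what, detail) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop_validation(sprintf("row %d: %s (%s)", idx[1], what, detail(idx[1])))
    }
  }
  bad_row(!tr$section %in% .SECTIONS, "unknown section",
          function(i) tr$section[i])
  bad_row(!tr$ink_color %in% .INK_COLORS, "invalid ink colour",
          function(i) tr$ink_color[i])
  lat <- suppressWarnings(as.numeric(tr$latency_ms))
  bad_row(is.na(lat), "non-numeric latency",
          function(i) as.character(trials$latency_ms[i]))
  bad_row(!is.finite(lat) | lat <= 0, "latency must be finite and positive",
          function(i) format(lat[i]))
  tr$latency_ms <- lat

  key_wl <- paste(wl$section, wl$text, sep = "\r")
  key_tr <- paste(tr$section, tr$word, sep = "\r")
  bad_row(!key_tr %in% key_wl, "word not in word list for its section",
          function(i) sprintf("%s / %s", tr$section[i], tr$word[i]))

  dup_key <- paste(tr$participant_id, tr$word, tr$section, tr$ink_color,
                   sep = "\r")
  bad_row(duplicated(dup_key), "duplicate (participant, word, colour) trial",
          function(i) sprintf("%s / %s / %s", tr$participant_id[i],
                              tr$word[i], tr$ink_color[i]))
  tr$trial_index <- as.integer(tr$trial_index)
  if (anyNA(tr$trial_index) || any(tr$trial_index < 0)) {
    stop_validation("trial_index must be a non-negative integer")
  }
  tr
}

#' Read or write a trial log (CSV)
#'
#' One row per stimulus presentation; columns `participant_id`, `section`,
#' `word`, `ink_color`, `latency_ms`, `trial_index`. UTF-8, comma-separated,
#' header mandatory. Reading validates every row against the word list;
#' file row order is preserved in the returned tibble.
#'
#' @param path File path.
#' @param word_list Validated word list.
#' @param trials Trial tibble (for writing).
#' @return `read_trial_log()` returns a validated trial tibble;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
read_trial_log <- function(path, word_list) {
  if (!file.exists(path)) {
    stop_validation(sprintf("trial log not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  validate_trials(raw, word_list)
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials[, .TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write participant metadata (CSV)
#'
#' Metadata CSV columns: `participant_id`, `diagnosis` (one of `adhd`,
#' `control`, `excluded_suspected`), `screener_score`. Valence ratings live
#' in a companion long CSV (`participant_id`, `word`, `rating` in -3..+3),
#' one row per rated emotion word. Participants flagged
#' `excluded_suspected` (self-suspected undiagnosed cases) stay first-class
#' — individual reports are still produced for them — but group analyses
#' skip them.
#'
#' @param path Metadata CSV path.
#' @param ratings_path Optional companion ratings CSV path.
#' @param participants,ratings Tibbles (for writing).
#' @return `read_participants()` returns `list(participants, ratings)`
#'   (ratings `NULL` when no path given); the writer returns paths invisibly.
#' @export
read_participants <- function(path, ratings_path = NULL) {
  if (!file.exists(path)) {
    stop_validation(sprintf("participant metadata not found: %s", path))
  }
  meta <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("participant_id", "diagnosis", "screener_score")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop_validation(sprintf("participant metadata missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  meta$participant_id <- as.character(meta$participant_id)
  bad <- setdiff(unique(meta$diagnosis), .DIAGNOSES)
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown diagnosis value(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(meta$participant_id)) {
    stop_validation("duplicate participant_id in metadata")
  }
  if (any(!is.finite(meta$screener_score) | meta$screener_score < 0)) {
    stop_validation("screener_score must be finite and non-negative")
  }
  ratings <- NULL
  if (!is.null(ratings_path)) {
    if (!file.exists(ratings_path)) {
      stop_validation(sprintf("ratings file not found: %s", ratings_path))
    }
    ratings <- tibble::as_tibble(utils::read.csv(ratings_path,
                                                 stringsAsFactors = FALSE))
    needr <- c("participant_id", "word", "rating")
    if (length(setdiff(needr, names(ratings))) > 0) {
      stop_validation("ratings file must have participant_id, word, rating")
    }
    ratings$participant_id <- as.character(ratings$participant_id)
    ratings$word <- normalize_word(as.character(ratings$word))
    if (any(!is.finite(ratings$rating) |
            ratings$rating < -3 | ratings$rating > 3)) {
      stop_validation("ratings must lie in [-3, 3]")
    }
  }
  list(participants = meta, ratings = ratings)
}

#' @rdname read_participants
#' @export
write_participants <- function(participants, path,
                               ratings = NULL, ratings_path = NULL) {
  utils::write.csv(
    participants[, c("participant_id", "diagnosis", "screener_score")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(ratings)) {
    if (is.null(ratings_path)) stop_domain("ratings given without ratings_path")
    utils::write.csv(ratings[, c("participant_id", "word", "rating")],
                     ratings_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write or read a per-participant interest report (JSON)
#'
#' The report is the therapist-facing artefact: the participant's flagged
#' words ranked by z (descending), every per-(section, category) percentage,
#' the threshold used, the headline daily-life issue count, and a
#' provenance block (input files, config hash, generator seed when the data
#' are synthetic). `read_interest_report()` reconstructs a value-identical
#' [interest_profile] object.
#'
#' @param profile An [interest_profile] object.
#' @param path File path.
#' @param provenance Named list stored verbatim in the report.
#' @return The writer returns `path` invisibly; the reader an
#'   `interest_profile`.
#' @export
write_interest_report <- function(profile, path, provenance = list()) {
  stopifnot(inherits(profile, "interest_profile"))
  payload <- list(
    participant_id = profile$participant_id,
    z_threshold = profile$z_threshold,
    n_issues = profile$n_issues,
    flagged_words = profile$flagged_words,
    category_percentages = profile$category_percentages,
    provenance = provenance)
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) {
                    rlang::abort(sprintf("cannot write report: %s", path),
                                 class = "stroopwoi_io_error", parent = e)
                  })
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, na = "null", pretty = TRUE), con)
  invisible(path)
}

#' @rdname write_interest_report
#' @export
read_interest_report <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("report not found: %s", path))
  }
  obj <- jsonlite::fromJSON(path)
  flagged <- tibble::as_tibble(obj$flagged_words)
  if (nrow(flagged) == 0) {
    flagged <- tibble::tibble(word = character(), section = character(),
                              category = character(), z = numeric())
  }
  perc <- tibble::as_tibble(obj$category_percentages)
  new_interest_profile(
    participant_id = obj$participant_id,
    z_threshold = obj$z_threshold,
    flagged_words = flagged,
    category_percentages = perc)
}
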