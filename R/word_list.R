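#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Section and category vocabularies shared by every stage of the pipeline.
## The task has eight rounds: one on personality traits, one on emotions,
## five on daily-life domains (work/study, relationships/family, social
## connections, hobbies/free time, self-image/confidence), plus a practice
## round that never reaches analysis.

.SECTIONS <- c("personality", "emotion",
               "work", "relationships", "social", "hobby", "self_image")
.TOPIC_CATEGORIES <- c("related", "unrelated", "distraction")
.EMOTION_CATEGORIES <- c("positive", "neutral", "negative", "distraction")
.INK_COLORS <- c("red", "blue")
.DIAGNOSES <- c("adhd", "control", "excluded_suspected")

#' Task sections
#'
#' @description
#' `stroop_sections()` returns all seven analysed task sections;
#' `daily_life_sections()` returns the five daily-life domains (the 50-word
#' issue inventory when each domain carries 10 words).
#'
#' @return Character vector of section names.
#' @export
stroop_sections <- function() .SECTIONS

#' @rdname stroop_sections
#' @export
daily_life_sections <- function() .SECTIONS[3:7]

#' Word categories valid for a section
#'
#' The emotion section uses valence categories (positive / neutral /
#' negative, plus distraction fillers); every other section uses topical
#' categories (related / unrelated / distraction).
#'
#' @param section A section name.
#' @return Character vector of valid categories.
#' @export
section_categories <- function(section) {
  section <- match.arg(section, .SECTIONS)
  if (section == "emotion") .EMOTION_CATEGORIES else .TOPIC_CATEGORIES
}

## Word identity: Unicode NFC + trimmed, no case folding (stimuli may be
## case-sensitive in the stimulus language).
normalize_word <- function(x) stringi::stri_trans_nfc(trimws(x))

stop_validation <- function(msg, ...) {
  rlang::abort(msg, class = "stroopwoi_validation_error", ...)
}

stop_domain <- function(msg, ...) {
  rlang::abort(msg, class = "stroopwoi_domain_error", ...)
}

#' Validate a word-list table
#'
#' A word list is the stimulus configuration: one row per word with its
#' section, category and (optionally) a 1-7 norm valence from the selection
#' norms. Invariants enforced: known section and category, category valid
#' for the section, non-empty word text unique within a section, and norm
#' valence inside \[1, 7\] where present.
#'
#' @param word_list Data frame with columns `text`, `section`, `category`,
#'   and optionally `norm_valence`.
#' @return The validated word list as a tibble (text normalised, invisibly
#'   usable downstream).
#' @export
validate_word_list <- function(word_list) {
  required <- c("text", "section", "category")
  missing <- setdiff(required, names(word_list))
  if (length(missing) > 0) {
    stop_validation(sprintf("word list is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  wl <- tibble::as_tibble(word_list)
  if (!"norm_valence" %in% names(wl)) wl$norm_valence <- NA_real_
  wl$text <- normalize_word(as.character(wl$text))
  if (any(!nzchar(wl$text))) {
    stop_validation("word list contains empty word text")
  }
  bad_sec <- setdiff(unique(wl$section), .SECTIONS)
  if (length(bad_sec) > 0) {
    stop_validation(sprintf("unknown section(s): %s",
                            paste(bad_sec, collapse = ", ")))
  }
  for (sec in unique(wl$section)) {
    ok <- section_categories(sec)
    bad <- setdiff(unique(wl$category[wl$section == sec]), ok)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "section '%s' contains invalid category(ies): %s",
        sec, paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(wl$text[wl$section == sec])) {
      dup <- wl$text[wl$section == sec]
      dup <- unique(dup[duplicated(dup)])
      stop_validation(sprintf("duplicate word(s) in section '%s': %s",
                              sec, paste(dup, collapse = ", ")))
    }
  }
  nv <- wl$norm_valence[!is.na(wl$norm_valence)]
  if (any(nv < 1 | nv > 7)) {
    stop_validation("norm_valence values must lie in [1, 7]")
  }
  wl
}

#' Build a synthetic placeholder word list
#'
#' The study's stimulus inventory is language-specific and not bundled; this
#' constructor builds a structurally equivalent synthetic list: one
#' personality round with related/unrelated/distraction words, one emotion
#' round with positive/neutral/negative words (rated by participants), and
#' five daily-life domains whose words form the issue inventory (10 words
#' per domain gives the 50-word inventory).
#'
#' Norm valences (1-7 selection-norm scale) are assigned on conventional
#' bands: positive words 5.5-6.5, neutral and distraction words 3.5-4.5
#' (the neutral selection band), negative words 1.5-2.5.
#'
#' @param personality_per_category Words per category in the personality
#'   round (default 10).
#' @param emotion_per_valence Words per valence class in the emotion round
#'   (default 8, giving 24 rated emotion words).
#' @param words_per_domain Words in each daily-life domain (default 10).
#' @param domain_split Named integer vector splitting each domain's words
#'   into related / unrelated / distraction; must sum to `words_per_domain`.
#' @return Tibble with columns `text`, `section`, `category`, `norm_valence`.
#' @export
#' @examples
#' wl <- make_word_list()
#' table(wl$section)
make_word_list <- function(personality_per_category = 10,
                           emotion_per_valence = 8,
                           words_per_domain = 10,
                           domain_split = c(related = 4, unrelated = 3,
                                            distraction = 3)) {
  if (words_per_domain > 0) {
    if (!setequal(names(domain_split), .TOPIC_CATEGORIES)) {
      stop_domain("domain_split must name related, unrelated and distraction")
    }
    if (sum(domain_split) != words_per_domain) {
      stop_domain("domain_split must sum to words_per_domain")
    }
  }
  band <- function(n, lo, hi) {
    if (n == 1) return((lo + hi) / 2)
    seq(lo, hi, length.out = n)
  }
  rows <- list()
  mk <- function(section, category, n, valence = NULL) {
    if (n == 0) return(NULL)
    tibble::tibble(
      text = sprintf("%s_%s_%02d", section, category, seq_len(n)),
      section = section,
      category = category,
      norm_valence = if (is.null(valence)) rep(NA_real_, n) else valence)
  }
  if (personality_per_category > 0) {
    for (cat in .TOPIC_CATEGORIES) {
      v <- if (cat == "distraction") {
        band(personality_per_category, 3.5, 4.5)
      } else NULL
      rows <- c(rows, list(mk("personality", cat, personality_per_category, v)))
    }
  }
  if (emotion_per_valence > 0) {
    rows <- c(rows, list(
      mk("emotion", "positive", emotion_per_valence,
         band(emotion_per_valence, 5.5, 6.5)),
      mk("emotion", "neutral", emotion_per_valence,
         band(emotion_per_valence, 3.5, 4.5)),
      mk("emotion", "negative", emotion_per_valence,
         band(emotion_per_valence, 1.5, 2.5))))
  }
  if (words_per_domain > 0) {
    for (sec in daily_life_sections()) {
      for (cat in .TOPIC_CATEGORIES) {
        n <- unname(domain_split[[cat]])
        v <- if (cat == "distraction") band(max(n, 1), 3.5, 4.5)[seq_len(n)] else NULL
        rows <- c(rows, list(mk(sec, cat, n, v)))
      }
    }
  }
  wl <- dplyr::bind_rows(rows)
  if (nrow(wl) == 0) stop_domain("word list would be empty")
  validate_word_list(wl)
}

#' Read or write a word-list configuration (JSON)
#'
#' The on-disk dialect is a JSON array of objects with fields `text`,
#' `section`, `category` and optional `norm_valence`.
#'
#' @param path File path.
#' @param word_list Word-list tibble (for writing).
#' @return `read_word_list()` returns a validated tibble;
#'   `write_word_list()` returns `path` invisibly.
#' @export
read_word_list <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("word list file not found: %s", path))
  }
  wl <- jsonlite::fromJSON(path)
  validate_word_list(wl)
}

#' @rdname read_word_list
#' @export
write_word_list <- function(word_list, path) {
  wl <- validate_word_list(word_list)
  jsonlite::write_json(wl, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Rescale a 1-7 norm valence to the participant rating scale
#'
#' Selection norms score valence on 1-7; participants rate the emotion
#' words on -3 to +3. The linear map `x - 4` sends the 1-7 midpoint (4,
#' neutral) to 0 and the endpoints to -3/+3; the neutral selection band
#' 3.5-4.5 maps to -0.5 to +0.5.
#'
#' @param norm_value Numeric vector on the 1-7 scale.
#' @return Numeric vector on the -3 to +3 scale.
#' @export
#' @examples
#' rescale_valence(c(1, 4, 7))  # -3 0 3
rescale_valence <- function(norm_value) {
  if (!is.numeric(norm_value)) stop_domain("norm_value must be numeric")
  if (any(is.na(norm_value)) || any(norm_value < 1 | norm_value > 7)) {
    stop_domain("norm_value must lie in [1, 7]")
  }
  norm_value - 4
}
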