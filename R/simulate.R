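## Synthetic cohort generator. Emulates the task design — every word shown
## once in red and once in blue, eight rounds (personality, emotion, five
## daily-life domains) — with:
##   * between-participant baseline heterogeneity (Gaussian, sd 80 ms),
##   * ex-Gaussian trial noise (Gaussian mu/sigma convolved with an
##     exponential tail tau; the standard right-skewed RT model),
##   * a linear valence model on rated emotion words
##     (latency ~ b_valence*v + b_diagnosis*d + b_interaction*v*d),
##   * a mean shift on ADHD-related words for ADHD participants,
##   * planted high-latency "issue" words in the daily-life inventory,
##   * rare extreme-latency contamination triggering both outlier rules.
## Ground truth is emitted alongside the data and never consumed by the
## pipeline under test.

#' Configuration of a synthetic Stroop cohort
#'
#' Defaults give a 60+60 cohort over the full task: 30 personality words
#' (10 per category), 24 rated emotion words (8 per valence class), and the
#' 50-word daily-life inventory (10 words in each of 5 domains). Trial
#' noise is ex-Gaussian with mu 500 ms, sigma 60 ms, tau 100 ms (mean
#' latency mu + tau); participant baselines vary with SD 80 ms. The valence
#' model uses coefficients 2.68 (valence), 20.89 (diagnosis), -8.36
#' (valence x diagnosis) ms. Each ADHD participant receives `planted_k`
#' issue words (spread over distinct domains) shifted upward by
#' `planted_shift_sd` within-participant word-mean SDs, where that SD is
#' sqrt((sigma^2 + tau^2) / 2) for a two-trial word mean. Contamination
#' injects latencies in 4000-6000 ms at `contamination_slow_rate` and
#' 5-95 ms at `contamination_fast_rate` per trial.
#'
#' @param n_adhd,n_control,n_excluded Participants per diagnosis state.
#' @param personality_per_category,emotion_per_valence,words_per_domain,domain_split
#'   Word-list dimensions, passed to [make_word_list()].
#' @param mu_ms,sigma_ms,tau_ms Ex-Gaussian trial-noise parameters (ms).
#' @param baseline_sd_ms Between-participant baseline SD (ms).
#' @param b_valence,b_diagnosis,b_interaction Valence-model coefficients
#'   (ms per unit; diagnosis coded control = 0, ADHD = 1).
#' @param b_related_ms Mean slow-down of ADHD participants on related words
#'   (personality and daily-life), ms.
#' @param planted_k Planted issue words per ADHD participant.
#' @param planted_shift_sd Planted shift in within-participant word-mean
#'   SDs.
#' @param rating_noise_sd SD of the Gaussian noise added to rescaled norm
#'   valences before rounding/clipping into the -3..+3 rating.
#' @param contamination_slow_rate,contamination_fast_rate Per-trial
#'   probabilities of extreme slow / fast contamination.
#' @param screener_mean_adhd,screener_mean_control,screener_sd Screener
#'   totals are drawn from two overlapping normals (truncated at 0).
#' @param seed Integer seed; drives per-participant substreams so extending
#'   a cohort never reshuffles existing participants.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_adhd = 60, n_control = 60, n_excluded = 0,
                          personality_per_category = 10,
                          emotion_per_valence = 8,
                          words_per_domain = 10,
                          domain_split = c(related = 4, unrelated = 3,
                                           distraction = 3),
                          mu_ms = 500, sigma_ms = 60, tau_ms = 100,
                          baseline_sd_ms = 80,
                          b_valence = 2.68, b_diagnosis = 20.89,
                          b_interaction = -8.36,
                          b_related_ms = 30,
                          planted_k = 3, planted_shift_sd = 3.0,
                          rating_noise_sd = 0.7,
                          contamination_slow_rate = 0.002,
                          contamination_fast_rate = 0.0005,
                          screener_mean_adhd = 45,
                          screener_mean_control = 25,
                          screener_sd = 10,
                          seed = 1) {
  cfg <- as.list(environment())
  n_total <- n_adhd + n_control + n_excluded
  if (n_total <= 0) stop_domain("cohort must contain at least one participant")
  n_words <- 3 * personality_per_category + 3 * emotion_per_valence +
    5 * words_per_domain
  if (n_words <= 0) stop_domain("cohort must contain at least one word")
  if (any(c(sigma_ms, tau_ms, baseline_sd_ms, rating_noise_sd) < 0)) {
    stop_domain("noise SDs must be non-negative")
  }
  if (any(c(contamination_slow_rate, contamination_fast_rate) < 0) ||
      contamination_slow_rate + contamination_fast_rate > 1) {
    stop_domain("contamination rates must be non-negative and sum to <= 1")
  }
  if (mu_ms <= 0) stop_domain("mu_ms must be positive")
  if (planted_k < 0 ||
      (words_per_domain > 0 && planted_k > 5 * words_per_domain)) {
    stop_domain("planted_k must lie in [0, daily-life inventory size]")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

## Within-participant SD of a two-trial word mean under ex-Gaussian noise.
word_mean_sd <- function(config) {
  sqrt((config$sigma_ms^2 + config$tau_ms^2) / 2)
}

participant_substream <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 10007 + index) %% 2147483647)
}

#' Draw a participant's valence ratings for the emotion words
#'
#' rating = clip(round(rescale_valence(norm) + noise), -3, +3): the 1-7 norm
#' valence is rescaled to -3..+3, perturbed with Gaussian noise (individual
#' taste), then rounded and clipped to the discrete survey scale. Uses the
#' current RNG state; the cohort generator calls it inside a participant's
#' substream.
#'
#' @param word_list Word list; only rated emotion words (positive / neutral
#'   / negative) are used, and each must carry a `norm_valence`.
#' @param rating_noise_sd Gaussian noise SD before rounding.
#' @return Tibble `word`, `rating` (integer -3..+3).
#' @export
generate_valence_ratings <- function(word_list, rating_noise_sd = 0.7) {
  ew <- word_list[word_list$section == "emotion" &
                    word_list$category %in%
                    c("positive", "neutral", "negative"), , drop = FALSE]
  if (nrow(ew) == 0) {
    return(tibble::tibble(word = character(), rating = integer()))
  }
  if (anyNA(ew$norm_valence)) {
    stop_domain("emotion words must carry norm_valence to be rated")
  }
  raw <- rescale_valence(ew$norm_valence) +
    stats::rnorm(nrow(ew), 0, rating_noise_sd)
  tibble::tibble(word = ew$text,
                 rating = as.integer(pmin(3, pmax(-3, round(raw)))))
}

rexgauss <- function(n, mu, sigma, tau) {
  g <- if (sigma > 0) stats::rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) stats::rexp(n, rate = 1 / tau) else 0
  g + e
}

#' Generate a synthetic Stroop cohort
#'
#' Produces trial logs, participant metadata, valence ratings, the word
#' list and a ground-truth bundle. Per word and participant, two trials
#' (red, blue) are drawn as participant baseline + structural effects +
#' ex-Gaussian noise; contamination then replaces a trial's latency at the
#' configured rates. The same seed yields byte-identical output, and each
#' participant has their own RNG substream derived from the global seed.
#'
#' @param config A [cohort_config()].
#' @return `list(trials, participants, ratings, word_list, truth)`; `truth`
#'   holds the generating coefficients, per-word expected latencies
#'   (mu + tau + baseline + effects), planted words with their shift, and
#'   the injected contamination — for recovery tests only, never consumed
#'   by the pipeline.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  wl <- make_word_list(
    personality_per_category = config$personality_per_category,
    emotion_per_valence = config$emotion_per_valence,
    words_per_domain = config$words_per_domain,
    domain_split = config$domain_split)
  diagnosis <- rep(c("adhd", "control", "excluded_suspected"),
                   times = c(config$n_adhd, config$n_control,
                             config$n_excluded))
  n_part <- length(diagnosis)
  ids <- sprintf("P%04d", seq_len(n_part))
  shift_ms <- config$planted_shift_sd * word_mean_sd(config)
  daily <- wl[wl$section %in% daily_life_sections(), , drop = FALSE]
  rated <- wl$section == "emotion" &
    wl$category %in% c("positive", "neutral", "negative")

  trial_list <- vector("list", n_part)
  rating_list <- vector("list", n_part)
  planted_list <- vector("list", n_part)
  expected_list <- vector("list", n_part)
  contam_list <- vector("list", n_part)
  screener <- numeric(n_part)

  for (i in seq_len(n_part)) {
    set.seed(participant_substream(config$seed, i))
    pid <- ids[i]
    diag01 <- as.numeric(diagnosis[i] == "adhd")
    baseline <- stats::rnorm(1, 0, config$baseline_sd_ms)
    sc_mean <- switch(diagnosis[i],
                      adhd = config$screener_mean_adhd,
                      control = config$screener_mean_control,
                      excluded_suspected =
                        (config$screener_mean_adhd +
                           config$screener_mean_control) / 2)
    screener[i] <- max(0, stats::rnorm(1, sc_mean, config$screener_sd))

    ratings <- generate_valence_ratings(wl, config$rating_noise_sd)
    rating_of <- stats::setNames(as.numeric(ratings$rating), ratings$word)

    planted <- character(0)
    if (diag01 == 1 && config$planted_k > 0 && nrow(daily) > 0) {
      doms <- sample(daily_life_sections())
      doms <- rep_len(doms, config$planted_k)
      planted <- unlist(lapply(unique(doms), function(d) {
        pool <- daily$text[daily$section == d]
        sample(pool, sum(doms == d))
      }), use.names = FALSE)
    }

    effect <- numeric(nrow(wl))
    effect[wl$category == "related"] <- diag01 * config$b_related_ms
    if (any(rated)) {
      v <- rating_of[wl$text[rated]]
      effect[rated] <- config$b_valence * v +
        config$b_diagnosis * diag01 + config$b_interaction * v * diag01
    }
    effect[wl$text %in% planted] <- effect[wl$text %in% planted] + shift_ms

    n_tr <- 2 * nrow(wl)
    structural <- rep(baseline + effect, each = 2)
    latency <- structural +
      rexgauss(n_tr, config$mu_ms, config$sigma_ms, config$tau_ms)
    u <- stats::runif(n_tr)
    slow <- u < config$contamination_slow_rate
    fast <- !slow & u < config$contamination_slow_rate +
      config$contamination_fast_rate
    latency[slow] <- stats::runif(sum(slow), 4000, 6000)
    latency[fast] <- stats::runif(sum(fast), 5, 95)
    latency <- pmax(latency, 1)

    tr <- tibble::tibble(
      participant_id = pid,
      section = rep(wl$section, each = 2),
      word = rep(wl$text, each = 2),
      ink_color = rep(c("red", "blue"), times = nrow(wl)),
      latency_ms = latency,
      contam = ifelse(slow, "slow", ifelse(fast, "fast", "none")))
    ## pseudo-random presentation order within each task round
    ord <- unlist(lapply(split(seq_len(n_tr), factor(tr$section,
                                                     levels = .SECTIONS)),
                         sample), use.names = FALSE)
    tr <- tr[ord, , drop = FALSE]
    tr$trial_index <- seq_len(n_tr) - 1L

    trial_list[[i]] <- tr
    ratings$participant_id <- pid
    rating_list[[i]] <- ratings
    if (length(planted) > 0) {
      planted_list[[i]] <- tibble::tibble(
        participant_id = pid, word = planted,
        section = wl$section[match(planted, wl$text)],
        shift_ms = shift_ms)
    }
    expected_list[[i]] <- tibble::tibble(
      participant_id = pid, word = wl$text, section = wl$section,
      expected_ms = config$mu_ms + config$tau_ms + baseline + effect)
    contam_list[[i]] <- tr[tr$contam != "none",
                           c("participant_id", "section", "word",
                             "ink_color", "trial_index", "contam")]
  }

  trials <- dplyr::bind_rows(trial_list)
  trials <- trials[, c("participant_id", "section", "word", "ink_color",
                       "latency_ms", "trial_index")]
  participants <- tibble::tibble(participant_id = ids, diagnosis = diagnosis,
                                 screener_score = screener)
  ratings <- dplyr::bind_rows(rating_list)
  ratings <- ratings[, c("participant_id", "word", "rating")]
  truth <- list(
    coefficients = list(b_valence = config$b_valence,
                        b_diagnosis = config$b_diagnosis,
                        b_interaction = config$b_interaction,
                        b_related_ms = config$b_related_ms),
    within_participant_sd = word_mean_sd(config),
    planted = dplyr::bind_rows(planted_list),
    expected = dplyr::bind_rows(expected_list),
    contamination = dplyr::bind_rows(contam_list),
    seed = config$seed)
  if (ncol(truth$planted) == 0) {
    truth$planted <- tibble::tibble(participant_id = character(),
                                    word = character(), section = character(),
                                    shift_ms = numeric())
  }
  list(trials = trials, participants = participants, ratings = ratings,
       word_list = wl, truth = truth)
}
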