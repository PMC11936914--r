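small_config <- function(seed = 7, ...) {
  cohort_config(n_adhd = 4, n_control = 4,
                personality_per_category = 3, emotion_per_valence = 3,
                words_per_domain = 4,
                domain_split = c(related = 2, unrelated = 1,
                                 distraction = 1),
                seed = seed, ...)
}

test_that("the same seed reproduces the cohort byte for byte", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$truth$planted, b$truth$planted)
  c <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$trials$latency_ms, c$trials$latency_ms))
})

test_that("extending the cohort never reshuffles existing participants", {
  small <- generate_cohort(cohort_config(n_adhd = 3, n_control = 0,
                                         words_per_domain = 4,
                                         domain_split = c(related = 2,
                                                          unrelated = 1,
                                                          distraction = 1),
                                         seed = 7))
  big <- generate_cohort(cohort_config(n_adhd = 6, n_control = 0,
                                       words_per_domain = 4,
                                       domain_split = c(related = 2,
                                                        unrelated = 1,
                                                        distraction = 1),
                                       seed = 7))
  ids <- unique(small$trials$participant_id)
  expect_identical(small$trials,
                   big$trials[big$trials$participant_id %in% ids, ])
})

test_that("a noise-free cohort hits its expected latencies exactly", {
  cfg <- small_config(sigma_ms = 0, tau_ms = 0, baseline_sd_ms = 0,
                      planted_k = 0, contamination_slow_rate = 0,
                      contamination_fast_rate = 0)
  cohort <- generate_cohort(cfg)
  joined <- dplyr::inner_join(cohort$trials, cohort$truth$expected,
                              by = c("participant_id", "word", "section"))
  expect_equal(joined$latency_ms, joined$expected_ms, tolerance = 1e-12)
  # red and blue agree word for word
  lat <- average_color_latencies(cohort$trials, cohort$word_list)
  expect_true(all(lat$n_colors_used == 2))
  key <- dplyr::inner_join(lat, cohort$truth$expected,
                           by = c("participant_id", "word", "section"))
  expect_equal(key$mean_latency_ms, key$expected_ms, tolerance = 1e-12)
})

test_that("each word appears once per colour per participant", {
  cohort <- generate_cohort(small_config())
  counts <- cohort$trials |>
    dplyr::count(participant_id, word, ink_color)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(cohort$trials),
               2 * nrow(cohort$word_list) * nrow(cohort$participants))
  # valid against the strict trial contract
  expect_silent(validate_trials(cohort$trials, cohort$word_list))
})

test_that("empirical mean latency matches the ex-Gaussian moment mu + tau", {
  cfg <- cohort_config(n_adhd = 0, n_control = 100,
                       personality_per_category = 0, emotion_per_valence = 0,
                       words_per_domain = 5,
                       domain_split = c(related = 2, unrelated = 2,
                                        distraction = 1),
                       baseline_sd_ms = 0, contamination_slow_rate = 0,
                       contamination_fast_rate = 0, seed = 13)
  cohort <- generate_cohort(cfg)   # 100 x 25 x 2 = 5000 trials, no effects
  n <- nrow(cohort$trials)
  se <- sqrt(cfg$sigma_ms^2 + cfg$tau_ms^2) / sqrt(n)
  expect_lt(abs(mean(cohort$trials$latency_ms) - (cfg$mu_ms + cfg$tau_ms)),
            3 * se)
})

test_that("valence ratings derive from rescaled norms", {
  wl <- make_word_list(emotion_per_valence = 4, words_per_domain = 0,
                       personality_per_category = 0)
  set.seed(17)
  noiseless <- generate_valence_ratings(wl, rating_noise_sd = 0)
  norm <- wl$norm_valence[match(noiseless$word, wl$text)]
  expect_equal(noiseless$rating,
               as.integer(pmin(3, pmax(-3, round(rescale_valence(norm))))))
  # endpoints: norm 7 -> +3, norm 4 -> 0 (exact words exist in a 1-word list)
  wl1 <- wl[c(which.max(wl$norm_valence)), ]
  wl1$norm_valence <- 7
  expect_equal(generate_valence_ratings(wl1, 0)$rating, 3L)
  wl1$norm_valence <- 4
  expect_equal(generate_valence_ratings(wl1, 0)$rating, 0L)
  # missing norm valence is an error
  wl_bad <- wl
  wl_bad$norm_valence[1] <- NA
  expect_error(generate_valence_ratings(wl_bad, 0),
               class = "stroopwoi_domain_error")
})

test_that("rating distribution is centred on the rescaled norm", {
  wl <- make_word_list(emotion_per_valence = 1, words_per_domain = 0,
                       personality_per_category = 0)
  target <- wl[wl$category == "neutral", ][1, ]  # norm 4 -> rescaled 0
  set.seed(19)
  draws <- vapply(1:1000, function(i) {
    generate_valence_ratings(wl, rating_noise_sd = 0.7)$rating[
      which(wl$text == target$text)]
  }, integer(1))
  expect_lt(abs(mean(draws) - rescale_valence(target$norm_valence)),
            3 * stats::sd(draws) / sqrt(length(draws)) + 0.05)
  expect_true(all(draws >= -3 & draws <= 3))
})

test_that("planted issues land on distinct daily-life domains with the configured shift", {
  cfg <- cohort_config(n_adhd = 10, n_control = 0, planted_k = 3, seed = 23)
  cohort <- generate_cohort(cfg)
  truth <- cohort$truth$planted
  expect_equal(nrow(truth), 30)
  per_part <- split(truth, truth$participant_id)
  for (p in per_part) {
    expect_equal(length(unique(p$section)), 3)
    expect_true(all(p$section %in% daily_life_sections()))
  }
  expect_equal(unique(truth$shift_ms),
               3.0 * sqrt((cfg$sigma_ms^2 + cfg$tau_ms^2) / 2))
  # the planted shift appears in the expected latencies
  joined <- dplyr::inner_join(
    truth, cohort$truth$expected, by = c("participant_id", "word", "section"))
  base <- dplyr::anti_join(
    cohort$truth$expected[cohort$truth$expected$section %in%
                            daily_life_sections(), ],
    truth[, c("participant_id", "word")], by = c("participant_id", "word"))
  expect_gt(min(joined$expected_ms) + 1e-9,
            min(base$expected_ms))
})

test_that("contamination audit counts match the generator's truth", {
  # near-deterministic noise so only injected trials can cross the rules
  cfg <- cohort_config(n_adhd = 0, n_control = 40,
                       personality_per_category = 5, emotion_per_valence = 0,
                       words_per_domain = 5,
                       domain_split = c(related = 2, unrelated = 2,
                                        distraction = 1),
                       sigma_ms = 5, tau_ms = 5, baseline_sd_ms = 10,
                       contamination_slow_rate = 0.01,
                       contamination_fast_rate = 0.005, seed = 29)
  cohort <- generate_cohort(cfg)
  pre <- preprocess_trials(cohort$trials, cohort$word_list, min_group = 2)
  contam <- cohort$truth$contamination
  n_fast <- sum(contam$contam == "fast")
  expect_equal(nrow(pre$dropped_fast), n_fast)
  # every word touched by a surviving slow trial is removed as a slow mean
  slow <- contam[contam$contam == "slow", ]
  fast_keys <- paste(contam$participant_id, contam$word)[
    contam$contam == "fast"]
  slow_words <- unique(slow[, c("participant_id", "word")])
  expect_equal(nrow(pre$dropped_slow), nrow(slow_words))
  expect_setequal(paste(pre$dropped_slow$participant_id,
                        pre$dropped_slow$word),
                  paste(slow_words$participant_id, slow_words$word))
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_adhd = 0, n_control = 0),
               class = "stroopwoi_domain_error")
  expect_error(cohort_config(personality_per_category = 0,
                             emotion_per_valence = 0, words_per_domain = 0),
               class = "stroopwoi_domain_error")
  expect_error(cohort_config(sigma_ms = -1),
               class = "stroopwoi_domain_error")
  expect_error(cohort_config(contamination_slow_rate = 0.9,
                             contamination_fast_rate = 0.2),
               class = "stroopwoi_domain_error")
})
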