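make_percentages <- function(n_per_group, means, sd = 5, seed = 1) {
  # means: named list means[[diagnosis]][category]
  set.seed(seed)
  rows <- list()
  for (diag in names(means)) {
    for (i in seq_len(n_per_group)) {
      pid <- paste0(diag, i)
      for (cat in names(means[[diag]])) {
        rows <- c(rows, list(tibble::tibble(
          participant_id = pid, diagnosis = diag, category = cat,
          percentage = stats::rnorm(1, means[[diag]][[cat]], sd))))
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the two-way ANOVA matches the from-scratch sums-of-squares oracle", {
  cats <- c("related", "unrelated", "distraction")
  for (seed in 1:8) {
    d <- make_percentages(12, list(
      adhd = stats::setNames(c(20, 10, 10) + seed, cats),
      control = stats::setNames(c(10, 10, 12), cats)), sd = 6, seed = seed)
    got <- anova_words_of_interest(d, threshold = 1.5)
    want <- oracle_anova_balanced(d$percentage, d$diagnosis, d$category)
    for (term in c("diagnosis", "category", "interaction")) {
      row <- got$terms[got$terms$term == term, ]
      expect_equal(row$F, unname(want$F[term]), tolerance = 1e-10)
      expect_equal(row$df, unname(want$df[term]))
      expect_equal(row$partial_eta_sq, unname(want$partial_eta_sq[term]),
                   tolerance = 1e-10)
      expect_gte(row$partial_eta_sq, 0)
      expect_lte(row$partial_eta_sq, 1)
    }
    expect_equal(got$df_error, want$df_error)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("a hand-sized 2x3 table reproduces the oracle decomposition", {
  # 2 participants per diagnosis, easy numbers
  d <- tibble::tibble(
    participant_id = rep(c("a1", "a2", "c1", "c2"), each = 3),
    diagnosis = rep(c("adhd", "adhd", "control", "control"), each = 3),
    category = rep(c("related", "unrelated", "distraction"), 4),
    percentage = c(30, 10, 10,  20, 10, 14,  10, 12, 10,  12, 8, 10))
  got <- anova_words_of_interest(d)
  want <- oracle_anova_balanced(d$percentage, d$diagnosis, d$category)
  expect_equal(got$terms$F,
               unname(want$F[c("diagnosis", "category", "interaction")]),
               tolerance = 1e-10)
})

test_that("identical group structures yield null-calibrated F statistics", {
  # no true effects: each F should fall below its 0.99 null quantile in
  # nearly all seeded runs
  cats <- c("related", "unrelated", "distraction")
  ok <- 0
  runs <- 40
  for (seed in seq_len(runs)) {
    d <- make_percentages(10, list(
      adhd = stats::setNames(c(10, 10, 10), cats),
      control = stats::setNames(c(10, 10, 10), cats)), sd = 4,
      seed = 1000 + seed)
    a <- anova_words_of_interest(d)
    crit <- stats::qf(0.99, a$terms$df, a$df_error)
    if (all(a$terms$F < crit)) ok <- ok + 1
  }
  expect_gte(ok / runs, 0.95 - 2 * sqrt(0.95 * 0.05 / runs))
})

test_that("ANOVA input contracts are enforced", {
  cats <- c("related", "unrelated", "distraction")
  one_group <- make_percentages(5, list(
    adhd = stats::setNames(c(10, 10, 10), cats)))
  expect_error(anova_words_of_interest(one_group),
               class = "stroopwoi_domain_error")
  both <- make_percentages(5, list(
    adhd = stats::setNames(c(10, 10, 10), cats),
    control = stats::setNames(c(10, 10, 10), cats)))
  missing_cell <- both[-1, ]
  expect_error(anova_words_of_interest(missing_cell),
               class = "stroopwoi_domain_error")
})

test_that("noise-free moderated regression recovers its generating coefficients", {
  grid <- expand.grid(valence = -3:3, diagnosis = c(0, 1),
                      rep = 1:3)
  d <- tibble::tibble(
    latency_ms = 600 + 2.68 * grid$valence + 20.89 * grid$diagnosis +
      (-8.36) * grid$valence * grid$diagnosis,
    valence = grid$valence, diagnosis = grid$diagnosis)
  fit <- suppressWarnings(moderated_regression(d))  # "essentially perfect fit"
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["intercept"]), 600, tolerance = 1e-8)
  expect_equal(unname(est["valence"]), 2.68, tolerance = 1e-8)
  expect_equal(unname(est["diagnosis"]), 20.89, tolerance = 1e-8)
  expect_equal(unname(est["valence_x_diagnosis"]), -8.36, tolerance = 1e-8)
  # implied valence slope inside the ADHD group
  expect_equal(unname(est["valence"] + est["valence_x_diagnosis"]), -5.68,
               tolerance = 1e-8)
})

test_that("regression CIs cover generating values at the nominal rate", {
  # noisy recovery: 95% CIs for the interaction should cover the truth at
  # ~95% over replicates
  b_int <- -8.36
  covered <- 0
  runs <- 300
  for (seed in seq_len(runs)) {
    set.seed(3000 + seed)
    n_part <- 40
    d <- dplyr::bind_rows(lapply(seq_len(n_part), function(i) {
      diag <- as.numeric(i <= n_part / 2)
      v <- sample(-3:3, 12, replace = TRUE)
      tibble::tibble(
        latency_ms = 600 + 2.68 * v + 20.89 * diag + b_int * v * diag +
          stats::rnorm(12, 0, 60),
        valence = v, diagnosis = diag)
    }))
    fit <- moderated_regression(d)
    row <- fit$coefficients[fit$coefficients$term == "valence_x_diagnosis", ]
    half <- stats::qt(0.975, fit$df_error) * row$se
    if (abs(row$estimate - b_int) <= half) covered <- covered + 1
  }
  expect_gte(covered / runs, 0.91)   # 95% minus 4 percentage points
  expect_lte(covered / runs, 0.99)
})

test_that("the interaction t statistic is calibrated against a permutation oracle", {
  set.seed(117)
  n_part <- 30
  words <- 8
  base <- dplyr::bind_rows(lapply(seq_len(n_part), function(i) {
    tibble::tibble(participant = i,
                   valence = sample(-3:3, words, replace = TRUE),
                   latency_ms = stats::rnorm(words, 600, 60))
  }))
  t_int <- function(labels) {
    d <- base
    d$diagnosis <- labels[d$participant]
    fit <- moderated_regression(d)
    fit$coefficients$t[fit$coefficients$term == "valence_x_diagnosis"]
  }
  perm_t <- vapply(1:300, function(i) {
    t_int(sample(rep(c(0, 1), n_part / 2)))
  }, numeric(1))
  # permutation distribution of the null t should match its reference t law
  ks <- stats::ks.test(perm_t, stats::pt, df = n_part * words - 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("regression rejects single-group input", {
  d <- tibble::tibble(latency_ms = stats::rnorm(20, 600, 10),
                      valence = rep(-3:3, length.out = 20), diagnosis = 1)
  expect_error(moderated_regression(d), class = "stroopwoi_domain_error")
})

test_that("confusion metrics satisfy their identities on all small tables", {
  # exhaustive over every 2x2 table with N <= 30 and both classes present
  grid <- expand.grid(tp = 0:30, fn = 0:30, fp = 0:30, tn = 0:30)
  grid <- grid[rowSums(grid) <= 30 &
                 (grid$tp + grid$fn) > 0 & (grid$fp + grid$tn) > 0, ]
  m <- classification_metrics(grid$tp, grid$fn, grid$fp, grid$tn)
  n <- unname(rowSums(grid))
  expect_equal(m$percent_correct, 100 * (grid$tp + grid$tn) / n)
  expect_equal(m$sensitivity, 100 * grid$tp / (grid$tp + grid$fn))
  expect_equal(m$specificity, 100 * grid$tn / (grid$tn + grid$fp))
  expect_true(all(m$percent_correct >= 0 & m$percent_correct <= 100))
  # spot-check against an explicit label-vector route
  set.seed(131)
  for (i in sample(nrow(grid), 50)) {
    g <- grid[i, ]
    truth <- c(rep(1, g$tp + g$fn), rep(0, g$fp + g$tn))
    pred <- c(rep(1, g$tp), rep(0, g$fn), rep(1, g$fp), rep(0, g$tn))
    expect_equal(classification_metrics(g$tp, g$fn, g$fp, g$tn)$percent_correct,
                 100 * mean(truth == pred))
  }
})

test_that("a degenerate all-control classifier scores sensitivity 0, specificity 100", {
  m <- classification_metrics(tp = 0, fn = 12, fp = 0, tn = 20)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  expect_equal(m$percent_correct, 100 * 20 / 32)
})

make_logit_cohort <- function(n_per_group, social_shift = 10, seed = 1) {
  set.seed(seed)
  doms <- c("perc_personality", "perc_work", "perc_relationships",
            "perc_social", "perc_hobby", "perc_self_image")
  d <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(2 * n_per_group)),
    diagnosis = rep(c("adhd", "control"), each = n_per_group))
  for (col in doms) d[[col]] <- pmax(0, stats::rnorm(nrow(d), 10, 5))
  # plant the signal in the social domain only (lower for ADHD)
  d$perc_social <- pmax(0, d$perc_social -
                          social_shift * (d$diagnosis == "adhd"))
  d$screener_score <- pmax(0, stats::rnorm(
    nrow(d), ifelse(d$diagnosis == "adhd", 45, 25), 10))
  d
}

test_that("odds ratios are exactly exp(coefficient)", {
  fit <- logistic_diagnosis_model(make_logit_cohort(40, seed = 5))
  expect_equal(fit$terms$odds_ratio, exp(fit$terms$coefficient),
               tolerance = 1e-12)
  expect_true(all(fit$terms$odds_ratio > 0))
})

test_that("a planted social-domain signal dominates the Wald statistics", {
  hits <- 0
  runs <- 100
  for (seed in seq_len(runs)) {
    fit <- suppressWarnings(
      logistic_diagnosis_model(make_logit_cohort(30, social_shift = 10,
                                                 seed = 5000 + seed)))
    t <- fit$terms[fit$terms$term != "(Intercept)", ]
    if (t$term[which.max(abs(t$wald_z))] == "perc_social" &&
        t$coefficient[t$term == "perc_social"] < 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / runs, 0.9)
})

test_that("adding the screener yields model 2 with an extra df and better fit", {
  d <- make_logit_cohort(40, seed = 7)
  m1 <- logistic_diagnosis_model(d, include_screener = FALSE)
  m2 <- logistic_diagnosis_model(d, include_screener = TRUE)
  expect_equal(m2$df, m1$df + 1)
  expect_gt(m2$pseudo_r2, m1$pseudo_r2)
  expect_true("screener_score" %in% m2$terms$term)
  expect_false("screener_score" %in% m1$terms$term)
})

test_that("threshold changes trade sensitivity against specificity monotonically", {
  d <- make_logit_cohort(40, seed = 9)
  ths <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  fits <- lapply(ths, function(th) {
    logistic_diagnosis_model(d, classification_threshold = th)
  })
  sens <- vapply(fits, `[[`, numeric(1), "sensitivity")
  spec <- vapply(fits, `[[`, numeric(1), "specificity")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("perfect separation is flagged but metrics are still reported", {
  d <- make_logit_cohort(15, social_shift = 60, seed = 11)
  d$perc_social <- ifelse(d$diagnosis == "adhd", 0, 60)  # fully separated
  expect_warning(fit <- logistic_diagnosis_model(d),
                 class = "stroopwoi_separation_warning")
  expect_false(fit$converged)
  expect_true(is.finite(fit$percent_correct))
  expect_equal(fit$percent_correct, 100)
})
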