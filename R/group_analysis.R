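## The three group-level models, with result objects shaped like the
## conventional reporting tables: per-term F / partial eta squared for the
## two-way ANOVA, coefficient / t / partial eta squared for the moderated
## regression, and odds ratio / Wald z plus confusion metrics for the
## logistic classifier. Fitting delegates to stats::lm / stats::glm and
## car::Anova; the derivations feeding and summarising them live here.

drop_excluded <- function(meta) {
  meta[meta$diagnosis != "excluded_suspected", , drop = FALSE]
}

partial_eta_sq <- function(ss_term, ss_error) ss_term / (ss_term + ss_error)

#' Two-way ANOVA on percentages of words of interest
#'
#' Diagnosis (ADHD vs control, between subjects) by word category (related /
#' unrelated / distraction, within subjects treated as independent cells)
#' on the percentage of words of interest. Type-II sums of squares: every
#' participant contributes all three categories, so imbalance arises only
#' between diagnosis groups, where type II is conventional. Effect size is
#' partial eta squared, SS_term / (SS_term + SS_error).
#'
#' @param percentages Tibble with columns `participant_id`, `diagnosis`
#'   (`adhd` / `control`), `category`, `percentage`; one row per
#'   participant-category.
#' @param threshold The z cut-off the percentages were computed at
#'   (recorded in the result).
#' @return A `stroop_anova` object: tibble `terms` (term, df, F,
#'   partial_eta_sq, p), `df_error`, `r_squared`, `threshold`.
#' @export
anova_words_of_interest <- function(percentages, threshold = NA_real_) {
  d <- tibble::as_tibble(percentages)
  d <- d[d$diagnosis %in% c("adhd", "control"), , drop = FALSE]
  if (length(unique(d$diagnosis)) < 2) {
    stop_domain("ANOVA needs both diagnosis groups")
  }
  cat_per_part <- table(d$participant_id)
  n_cat <- length(unique(d$category))
  if (n_cat < 2 || any(cat_per_part != n_cat)) {
    stop_domain("every participant must contribute one row per category")
  }
  if (min(table(unique(d[, c("participant_id", "diagnosis")])$diagnosis)) < 2) {
    stop_domain("need at least 2 participants per diagnosis group")
  }
  d$diagnosis <- factor(d$diagnosis, levels = c("control", "adhd"))
  d$category <- factor(d$category)
  fit <- stats::lm(percentage ~ diagnosis * category, data = d)
  aov2 <- car::Anova(fit, type = 2)
  ss <- aov2[["Sum Sq"]]
  names(ss) <- rownames(aov2)
  ss_err <- ss[["Residuals"]]
  term_map <- c(diagnosis = "diagnosis", category = "category",
                interaction = "diagnosis:category")
  terms <- tibble::tibble(
    term = names(term_map),
    df = vapply(term_map, function(t) aov2[t, "Df"], numeric(1),
                USE.NAMES = FALSE),
    F = vapply(term_map, function(t) aov2[t, "F value"], numeric(1),
               USE.NAMES = FALSE),
    partial_eta_sq = vapply(term_map, function(t) {
      partial_eta_sq(ss[[t]], ss_err)
    }, numeric(1), USE.NAMES = FALSE),
    p = vapply(term_map, function(t) aov2[t, "Pr(>F)"], numeric(1),
               USE.NAMES = FALSE))
  structure(list(terms = terms,
                 df_error = aov2["Residuals", "Df"],
                 r_squared = summary(fit)$r.squared,
                 threshold = threshold),
            class = "stroop_anova")
}

#' @export
print.stroop_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA on %% words of interest (z > %s), R^2 = %.3f\n",
              format(x$threshold), x$r_squared))
  t <- x$terms
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-12s F(%d,%d) = %6.2f, p = %.3f, eta_p^2 = %.3f\n",
                t$term[i], t$df[i], x$df_error, t$F[i], t$p[i],
                t$partial_eta_sq[i]))
  }
  invisible(x)
}

#' ANOVA sweep over the standard z cut-offs
#'
#' Recomputes flags, percentages and the two-way ANOVA at each cut-off
#' (default 0.5, 1.0, 1.5, 2.0) for one section's categories.
#'
#' @param z_scores Cohort z-scored latencies.
#' @param word_list Validated word list.
#' @param participants Participant metadata (excluded_suspected are
#'   dropped).
#' @param section Section to analyse (default `"personality"`).
#' @param thresholds Numeric vector of z cut-offs.
#' @return Named list of `stroop_anova` objects, one per threshold.
#' @export
anova_threshold_sweep <- function(z_scores, word_list, participants,
                                  section = "personality",
                                  thresholds = c(0.5, 1.0, 1.5, 2.0)) {
  meta <- drop_excluded(participants)
  res <- lapply(thresholds, function(th) {
    tab <- cohort_interest_table(
      z_scores[z_scores$participant_id %in% meta$participant_id, ,
               drop = FALSE],
      word_list, scoring_config(z_threshold = th))
    perc <- tab$percentages[tab$percentages$section == section, , drop = FALSE]
    perc <- dplyr::left_join(perc,
                             meta[, c("participant_id", "diagnosis")],
                             by = "participant_id")
    anova_words_of_interest(perc, threshold = th)
  })
  names(res) <- sprintf("z_%g", thresholds)
  res
}

#' Moderated regression of latency on word valence and diagnosis
#'
#' Ordinary least squares of word-level mean latency (ms) on the
#' participant's own valence rating of the word (-3..+3), diagnosis
#' (control = 0, ADHD = 1) and their product. A negative interaction means
#' the more negative the word, the slower ADHD participants respond
#' relative to controls. Partial eta squared per term uses type-II sums of
#' squares.
#'
#' @param data Tibble with columns `latency_ms`, `valence`, `diagnosis`
#'   (coded 0/1 or `"control"`/`"adhd"`), one row per rated word per
#'   participant.
#' @return A `stroop_modreg` object: tibble `coefficients` (term, estimate,
#'   se, t, p, partial_eta_sq), `model_f`, `df_model`, `df_error`,
#'   `r_squared`.
#' @export
moderated_regression <- function(data) {
  d <- tibble::as_tibble(data)
  if (is.character(d$diagnosis) || is.factor(d$diagnosis)) {
    d <- d[as.character(d$diagnosis) %in% c("adhd", "control"), ,
           drop = FALSE]
    d$diagnosis <- as.numeric(as.character(d$diagnosis) == "adhd")
  }
  if (length(unique(d$diagnosis)) < 2) {
    stop_domain("moderated regression needs both diagnosis groups")
  }
  fit <- stats::lm(latency_ms ~ valence * diagnosis, data = d)
  sm <- summary(fit)
  ## type-II sums of squares by model comparison (each term against the
  ## model without it, respecting marginality for the interaction)
  rss <- function(formula) stats::deviance(stats::lm(formula, data = d))
  rss_full <- stats::deviance(fit)
  rss_vd <- rss(latency_ms ~ valence + diagnosis)
  ss_int <- rss_vd - rss_full
  ss_val <- rss(latency_ms ~ diagnosis) - rss_vd
  ss_diag <- rss(latency_ms ~ valence) - rss_vd
  term_lm <- c(intercept = "(Intercept)", valence = "valence",
               diagnosis = "diagnosis",
               valence_x_diagnosis = "valence:diagnosis")
  co <- sm$coefficients
  eta <- c(intercept = NA_real_,
           valence = partial_eta_sq(ss_val, rss_full),
           diagnosis = partial_eta_sq(ss_diag, rss_full),
           valence_x_diagnosis = partial_eta_sq(ss_int, rss_full))
  coefficients <- tibble::tibble(
    term = names(term_lm),
    estimate = unname(co[term_lm, "Estimate"]),
    se = unname(co[term_lm, "Std. Error"]),
    t = unname(co[term_lm, "t value"]),
    p = unname(co[term_lm, "Pr(>|t|)"]),
    partial_eta_sq = unname(eta))
  fstat <- sm$fstatistic
  structure(list(coefficients = coefficients,
                 model_f = unname(fstat["value"]),
                 df_model = unname(fstat["numdf"]),
                 df_error = unname(fstat["dendf"]),
                 r_squared = sm$r.squared,
                 fit = fit),
            class = "stroop_modreg")
}

#' @export
print.stroop_modreg <- function(x, ...) {
  cat(sprintf(
    "Moderated regression: latency ~ valence * diagnosis\n  R^2 = %.3f, F(%d,%d) = %.2f\n",
    x$r_squared, x$df_model, x$df_error, x$model_f))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-20s %8.3f ms/unit  t = %6.2f\n", co$term[i],
                co$estimate[i], co$t[i]))
  }
  invisible(x)
}

#' Assemble the word-level dataset for the moderated regression
#'
#' Joins emotion-section word means (positive / neutral / negative words
#' only — unrated distraction fillers are excluded) with the participant's
#' own valence ratings and diagnosis. `excluded_suspected` participants are
#' dropped.
#'
#' @param word_latencies Word-latency tibble (post filters).
#' @param ratings Long ratings tibble (`participant_id`, `word`, `rating`).
#' @param participants Participant metadata.
#' @return Tibble `participant_id`, `word`, `latency_ms`, `valence`,
#'   `diagnosis`.
#' @export
emotion_regression_data <- function(word_latencies, ratings, participants) {
  meta <- drop_excluded(participants)
  d <- word_latencies[word_latencies$section == "emotion" &
                        word_latencies$category %in%
                        c("positive", "neutral", "negative"), , drop = FALSE]
  d <- dplyr::inner_join(d, ratings, by = c("participant_id", "word"))
  d <- dplyr::inner_join(d, meta[, c("participant_id", "diagnosis")],
                         by = "participant_id")
  tibble::tibble(participant_id = d$participant_id, word = d$word,
                 latency_ms = d$mean_latency_ms, valence = d$rating,
                 diagnosis = d$diagnosis)
}

#' Confusion-matrix metrics on the percentage scale
#'
#' Sensitivity = 100 TP / (TP + FN), specificity = 100 TN / (TN + FP),
#' percent correct = 100 (TP + TN) / N, with the diagnosed (ADHD) class
#' positive.
#'
#' @param tp,fn,fp,tn Cell counts of the 2x2 classification table.
#' @return List `sensitivity`, `specificity`, `percent_correct` (0-100;
#'   `NaN` when a class is empty).
#' @export
classification_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       percent_correct = 100 * (tp + tn) / n)
}

#' Logistic diagnostic model from words-of-interest percentages
#'
#' Predicts diagnosis (ADHD = 1) from the percentage of words of interest
#' on ADHD-related personality traits and in each of the five daily-life
#' domains; optionally adds the screener total (model 2). Percentages
#' enter as proportions (0-1), so each odds ratio is per full-scale change
#' of a predictor — the scale on which issue-percentage odds ratios are
#' conventionally reported. Reports Wald z per predictor, the likelihood-
#' ratio chi-square against the intercept-only model, McFadden pseudo-R²,
#' and sensitivity / specificity / percent correct at the classification
#' threshold. Perfect separation is flagged (`converged = FALSE`) with
#' metrics still computed from the achieved predictions.
#'
#' @param predictors Tibble with `participant_id`, `diagnosis`, one column
#'   per predictor percentage (0-100 scale), optionally `screener_score`.
#' @param include_screener Add `screener_score` as a predictor.
#' @param classification_threshold Predicted-probability cut-off for the
#'   confusion metrics (default 0.5).
#' @return A `stroop_logit` object: tibble `terms` (term, odds_ratio,
#'   coefficient, se, wald_z, p), `lr_chisq`, `df`, `lr_p`, `pseudo_r2`,
#'   `sensitivity`, `specificity`, `percent_correct`,
#'   `classification_threshold`, `converged`, `n`.
#' @export
logistic_diagnosis_model <- function(predictors, include_screener = FALSE,
                                     classification_threshold = 0.5) {
  if (classification_threshold <= 0 || classification_threshold >= 1) {
    stop_domain("classification_threshold must lie in (0, 1)")
  }
  d <- tibble::as_tibble(predictors)
  d <- d[d$diagnosis %in% c("adhd", "control"), , drop = FALSE]
  if (length(unique(d$diagnosis)) < 2) {
    stop_domain("logistic model needs both diagnosis groups")
  }
  y <- as.numeric(d$diagnosis == "adhd")
  perc_cols <- setdiff(names(d), c("participant_id", "diagnosis",
                                   "screener_score"))
  x <- as.data.frame(d[, perc_cols, drop = FALSE]) / 100  # proportions
  if (include_screener) {
    if (!"screener_score" %in% names(d)) {
      stop_domain("include_screener = TRUE but no screener_score column")
    }
    x$screener_score <- d$screener_score
  }
  dat <- cbind(data.frame(.y = y), x)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  ## a (near-)zero deviance means the classes are perfectly separated and
  ## the MLE does not exist, even when IRLS reports convergence
  converged <- fit$converged && !sep_warned && fit$deviance > 1e-6
  if (!converged) {
    rlang::warn("possible separation / non-convergence in logistic fit; metrics reported from achieved predictions",
                class = "stroopwoi_separation_warning")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- tibble::tibble(
    term = rownames(co),
    odds_ratio = exp(co[, "Estimate"]),
    coefficient = co[, "Estimate"],
    se = co[, "Std. Error"],
    wald_z = co[, "z value"],
    p = co[, "Pr(>|z|)"])
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(.y ~ 1, data = dat, family = stats::binomial())))
  prob <- stats::fitted(fit)
  pred <- prob > classification_threshold
  cm <- classification_metrics(tp = sum(pred & y == 1),
                               fn = sum(!pred & y == 1),
                               fp = sum(pred & y == 0),
                               tn = sum(!pred & y == 0))
  structure(list(terms = terms,
                 lr_chisq = fit$null.deviance - fit$deviance,
                 df = length(stats::coef(fit)) - 1,
                 lr_p = stats::pchisq(fit$null.deviance - fit$deviance,
                                      df = length(stats::coef(fit)) - 1,
                                      lower.tail = FALSE),
                 pseudo_r2 = 1 - ll / ll0,
                 sensitivity = cm$sensitivity,
                 specificity = cm$specificity,
                 percent_correct = cm$percent_correct,
                 classification_threshold = classification_threshold,
                 converged = converged,
                 n = length(y),
                 fit = fit),
            class = "stroop_logit")
}

#' @export
print.stroop_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic diagnosis model (n = %d): LR chi^2(%d) = %.2f, p = %.3f, McFadden R^2 = %.3f\n",
    x$n, x$df, x$lr_chisq, x$lr_p, x$pseudo_r2))
  t <- x$terms[x$terms$term != "(Intercept)", , drop = FALSE]
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-24s OR = %10.4g  z = %6.2f\n", t$term[i],
                t$odds_ratio[i], t$wald_z[i]))
  }
  cat(sprintf(
    "  sensitivity %.1f%%, specificity %.1f%%, correctly classified %.1f%% (threshold %.2f)\n",
    x$sensitivity, x$specificity, x$percent_correct,
    x$classification_threshold))
  invisible(x)
}

#' Build the wide predictor table for the logistic model
#'
#' One row per (non-excluded) participant: the percentage of words of
#' interest on ADHD-related personality traits (`perc_personality`) and
#' across all words of each daily-life domain (`perc_work`, ...,
#' `perc_self_image`), plus the screener total.
#'
#' @param percentages Long percentage tibble from [cohort_interest_table()].
#' @param participants Participant metadata.
#' @return Wide tibble ready for [logistic_diagnosis_model()].
#' @export
logistic_predictor_table <- function(percentages, participants) {
  meta <- drop_excluded(participants)
  p <- percentages[percentages$participant_id %in% meta$participant_id, ,
                   drop = FALSE]
  pers <- p[p$section == "personality" & p$category == "related", ,
            drop = FALSE]
  out <- tibble::tibble(participant_id = pers$participant_id,
                        perc_personality = pers$percentage)
  for (sec in daily_life_sections()) {
    dom <- p[p$section == sec, , drop = FALSE] |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(pp = 100 * sum(.data$n_flagged) / sum(.data$n_words),
                       .groups = "drop")
    names(dom)[2] <- paste0("perc_", sec)
    out <- dplyr::left_join(out, dom, by = "participant_id")
  }
  dplyr::inner_join(out,
                    meta[, c("participant_id", "diagnosis",
                             "screener_score")],
                    by = "participant_id")
}
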