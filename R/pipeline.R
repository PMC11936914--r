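## End-to-end driver: preprocess -> score -> group models, with optional
## artefact output. Deterministic: two runs on equal inputs and options
## produce identical results (timestamps live only in the audit log text).

#' Run the full words-of-interest pipeline
#'
#' Preprocesses the trial log, builds per-participant interest profiles
#' (including `excluded_suspected` participants, who get reports but are
#' skipped by every group model), sweeps the two-way ANOVA over the
#' standard cut-offs, fits the moderated valence regression (when ratings
#' are supplied) and the logistic diagnostic models (without and, when
#' screener scores are present, with the screener).
#'
#' @param trials Validated trial tibble (or a raw one; it is re-validated).
#' @param word_list Word list.
#' @param participants Participant metadata.
#' @param ratings Optional long valence-ratings tibble.
#' @param z_threshold Working cut-off for the profiles (default 1.5).
#' @param sweep_thresholds Cut-offs for the ANOVA sweep.
#' @param scope z-scoring scope (see [zscore_within_participant()]).
#' @param min_ms,max_ms Outlier-rule bounds.
#' @param classification_threshold Probability cut-off for the logistic
#'   confusion metrics.
#' @param out_dir Optional directory; when given, writes profiles
#'   (`profiles/<id>.json`), the cohort percentage table
#'   (`percentages.csv`), the audit table (`audit.csv`) and a results
#'   bundle (`group_analysis.json`).
#' @return `list(preprocessed, profiles, percentages, issue_counts, anova,
#'   regression, logistic)`.
#' @export
run_stroop_pipeline <- function(trials, word_list, participants,
                                ratings = NULL,
                                z_threshold = 1.5,
                                sweep_thresholds = c(0.5, 1.0, 1.5, 2.0),
                                scope = c("per_section", "all_sections"),
                                min_ms = 100, max_ms = 2000,
                                classification_threshold = 0.5,
                                out_dir = NULL) {
  scope <- match.arg(scope)
  wl <- validate_word_list(word_list)
  tr <- validate_trials(trials, wl)
  pre <- preprocess_trials(tr, wl, min_ms = min_ms, max_ms = max_ms,
                           scope = scope)
  config <- scoring_config(z_threshold = z_threshold)

  ids <- unique(participants$participant_id)
  profiles <- lapply(ids, function(pid) {
    build_interest_profile(pid, pre$z_scores, wl, config)
  })
  names(profiles) <- ids

  meta <- drop_excluded(participants)
  tab <- cohort_interest_table(
    pre$z_scores[pre$z_scores$participant_id %in% meta$participant_id, ,
                 drop = FALSE], wl, config)

  anova_res <- NULL
  if ("personality" %in% wl$section) {
    anova_res <- anova_threshold_sweep(pre$z_scores, wl, participants,
                                       thresholds = sweep_thresholds)
  }
  regression <- NULL
  if (!is.null(ratings) && "emotion" %in% wl$section) {
    regression <- moderated_regression(
      emotion_regression_data(pre$word_latencies, ratings, participants))
  }
  logistic <- NULL
  if (all(c("personality", daily_life_sections()) %in% wl$section)) {
    pred <- logistic_predictor_table(tab$percentages, participants)
    logistic <- list(
      model1 = logistic_diagnosis_model(
        pred, include_screener = FALSE,
        classification_threshold = classification_threshold),
      model2 = logistic_diagnosis_model(
        pred, include_screener = TRUE,
        classification_threshold = classification_threshold))
  }

  result <- list(preprocessed = pre, profiles = profiles,
                 percentages = tab$percentages,
                 issue_counts = tab$issue_counts,
                 anova = anova_res, regression = regression,
                 logistic = logistic)
  if (!is.null(out_dir)) {
    write_pipeline_artefacts(result, out_dir, z_threshold = z_threshold)
  }
  result
}

anova_to_list <- function(a) {
  list(threshold = a$threshold, r_squared = a$r_squared,
       df_error = a$df_error, terms = a$terms)
}

logit_to_list <- function(m) {
  list(terms = m$terms, lr_chisq = m$lr_chisq, df = m$df, lr_p = m$lr_p,
       pseudo_r2 = m$pseudo_r2, sensitivity = m$sensitivity,
       specificity = m$specificity, percent_correct = m$percent_correct,
       classification_threshold = m$classification_threshold,
       converged = m$converged, n = m$n)
}

write_pipeline_artefacts <- function(result, out_dir, z_threshold) {
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  for (pid in names(result$profiles)) {
    write_interest_report(result$profiles[[pid]],
                          file.path(out_dir, "profiles",
                                    paste0(pid, ".json")))
  }
  utils::write.csv(result$percentages,
                   file.path(out_dir, "percentages.csv"), row.names = FALSE)
  utils::write.csv(result$preprocessed$audit,
                   file.path(out_dir, "audit.csv"), row.names = FALSE)
  bundle <- list(z_threshold = z_threshold)
  if (!is.null(result$anova)) {
    bundle$anova <- lapply(result$anova, anova_to_list)
  }
  if (!is.null(result$regression)) {
    r <- result$regression
    bundle$moderated_regression <- list(
      coefficients = r$coefficients, model_f = r$model_f,
      df_model = r$df_model, df_error = r$df_error,
      r_squared = r$r_squared)
  }
  if (!is.null(result$logistic)) {
    bundle$logistic <- lapply(result$logistic, logit_to_list)
  }
  writeLines(jsonlite::toJSON(bundle, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, na = "null", pretty = TRUE),
             file.path(out_dir, "group_analysis.json"))
  invisible(out_dir)
}
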