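#' Run the full analysis pipeline
#'
#' Executes, in order: loading/validation, exclusions, utility construction,
#' the choice mixed model and its candidate-model comparison, per-subject
#' weights and dominance profiling, the stability block (when two
#' timepoints are present) and the psychopathology block (when a
#' questionnaire and factor weights are present). Inputs are either an
#' `info_bundle` from [generate_dataset()] / a generator config, or a named
#' list of CSV paths (`trials`, `participants`, and optionally `trials_t2`,
#' `questionnaire`, `factor_weights`).
#'
#' Every number in the emitted report is the value computed by the
#' corresponding module function; the reporting layer does no re-derivation.
#'
#' @param input an `info_bundle`, an `info_generator_config`, or a named
#'   list of file paths.
#' @param out_dir optional directory; when given, CSV/JSON report files are
#'   written there.
#' @param include_confidence include confidence-containing candidate models
#'   (default TRUE when a confidence column is present).
#' @param n_perm iterations for the stability permutation test.
#' @param min_trials minimum trials per participant per timepoint (see
#'   [apply_exclusions()]).
#' @param seed seed for the permutation draws.
#' @param ddf degrees-of-freedom method passed to [fit_mixed_model()].
#' @return a list of class `info_report` with elements `exclusions`,
#'   `descriptives`, `rating_correlations`, `fixed_effects`,
#'   `model_comparison`, `subject_weights`, `dominance`, `profile`,
#'   `midpoint`, `stability` (or NULL), `psych` (or NULL), `log`.
#' @export
run_pipeline <- function(input, out_dir = NULL, include_confidence = TRUE,
                         n_perm = 10000L, seed = 1L, min_trials = 20,
                         ddf = "satterthwaite") {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (inherits(input, "info_generator_config")) input <- generate_dataset(input)
  if (inherits(input, "info_bundle")) {
    trials <- input$trials_t1
    trials_t2 <- input$trials_t2
    participants <- input$participants
    questionnaire <- input$questionnaire
    factor_weights <- input$factor_weights
    note("input: synthetic bundle, seed ", input$config$seed)
  } else if (is.list(input)) {
    if (is.null(input$trials) || is.null(input$participants))
      stop("path input needs at least 'trials' and 'participants'",
           call. = FALSE)
    trials <- load_trials(input$trials)
    trials_t2 <- if (!is.null(input$trials_t2)) load_trials(input$trials_t2)
    participants <- load_participants(input$participants)
    questionnaire <- if (!is.null(input$questionnaire))
      load_questionnaire(input$questionnaire)
    factor_weights <- if (!is.null(input$factor_weights))
      load_factor_weights(input$factor_weights)
    note("input: files")
  } else stop("unrecognized input", call. = FALSE)

  all_trials <- rbind(trials, trials_t2)
  excl <- apply_exclusions(all_trials, participants, min_trials = min_trials)
  note("retained ", length(excl$retained), " of ", excl$n_input,
       " participants")
  kept <- retained_trials(all_trials, excl)
  ut <- center_within_participant(build_utilities(kept))
  tps <- unique(ut$timepoint)
  ut1 <- ut[ut$timepoint == tps[1], , drop = FALSE]

  desc_cols <- c("choice", "instrumental", "hedonic", "cognitive",
                 "confidence")
  descriptives <- do.call(rbind, lapply(desc_cols, function(col) data.frame(
    variable = col, mean = mean(ut1[[col]], na.rm = TRUE),
    sd = stats::sd(ut1[[col]], na.rm = TRUE), stringsAsFactors = FALSE)))
  rating_correlations <- stats::cor(ut1[desc_cols], use = "pairwise")

  has_conf <- !anyNA(ut1$confidence)
  specs <- enumerate_model_space(include_confidence && has_conf)
  fits <- lapply(specs, function(sp)
    fit_mixed_model(ut1, sp, ddf = if (identical(sp$label, "full")) ddf
                    else "none"))
  comparison <- compare_models(fits)
  full_fit <- fits[[which(vapply(specs, `[[`, "", "label") == "full")]]
  note("model comparison over ", length(fits), " specs; best BIC: ",
       comparison$best_bic)

  sw <- fit_subject_weights(ut)
  sw1 <- sw[sw$timepoint == tps[1], , drop = FALSE]
  dom <- classify_dominance(sw1)
  prof <- profile_summary(dom)
  mean_choice <- tapply(ut1$choice, ut1$participant_id, mean)
  midpoint <- midpoint_test(as.numeric(mean_choice))

  stability <- NULL
  if (length(tps) >= 2L) {
    w1 <- sw[sw$timepoint == tps[1], , drop = FALSE]
    w2 <- sw[sw$timepoint == tps[2], , drop = FALSE]
    stability <- list(
      permutation = permutation_stability_test(w1, w2, n_iter = n_perm,
                                               seed = seed),
      icc = icc_per_motive(w1, w2))
    note("stability block over ", length(intersect(w1$participant_id,
                                                   w2$participant_id)),
         " matched participants")
  } else note("single timepoint: stability block skipped")

  psych <- NULL
  if (!is.null(questionnaire) && !is.null(factor_weights)) {
    scores <- score_dimensions(questionnaire, factor_weights)
    scores <- scores[scores$participant_id %in% excl$retained, , drop = FALSE]
    psych <- list(
      scores = scores,
      ancova = ancova_dimensions(scores, sw, participants),
      regression = average_score_regression(scores, sw, participants),
      partial = partial_correlations(scores, sw, participants))
    if ("instrument" %in% names(questionnaire))
      psych$questionnaires <- questionnaire_associations(
        sw, questionnaire[questionnaire$participant_id %in% excl$retained, ],
        participants)
    note("psychopathology block over ", psych$regression$n,
         " complete participants")
  } else note("no questionnaire: psychopathology block skipped")

  report <- list(exclusions = excl, descriptives = descriptives,
                 rating_correlations = rating_correlations,
                 fixed_effects = full_fit$fixed_effects,
                 full_fit = full_fit,
                 model_comparison = comparison,
                 subject_weights = sw, dominance = dom, profile = prof,
                 midpoint = midpoint, stability = stability, psych = psych,
                 seed = seed, log = log)
  class(report) <- "info_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to CSV/JSON files
#'
#' @param report an `info_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "info_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  wr_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE); files <<- c(files, p)
  }
  wr_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, force = TRUE)
    files <<- c(files, p)
  }
  wr_csv(report$descriptives, "descriptives.csv")
  wr_csv(as.data.frame(report$rating_correlations), "rating_correlations.csv")
  wr_csv(report$fixed_effects, "fixed_effects.csv")
  wr_csv(report$model_comparison$table, "model_comparison.csv")
  wr_csv(report$subject_weights, "subject_weights.csv")
  wr_csv(report$dominance, "dominance_labels.csv")
  wr_json(list(by_motive = report$profile$by_motive,
               by_tier = report$profile$by_tier, n = report$profile$n),
          "dominance_summary.json")
  wr_json(list(excluded_attention = report$exclusions$excluded_attention,
               excluded_zero_variance = report$exclusions$excluded_zero_variance,
               retained = report$exclusions$retained),
          "exclusions.json")
  wr_json(report$midpoint, "midpoint_test.json")
  if (!is.null(report$stability)) {
    st <- report$stability
    wr_csv(st$permutation$per_subject, "stability_distances.csv")
    wr_json(list(actual_mean_distance = st$permutation$actual_mean_distance,
                 proportion_actual_smaller =
                   st$permutation$proportion_actual_smaller,
                 mean_difference = st$permutation$mean_difference,
                 difference_range = st$permutation$difference_range,
                 n_iter = st$permutation$n_iter, seed = st$permutation$seed),
            "stability_permutation.json")
    wr_csv(st$icc, "stability_icc.csv")
  }
  if (!is.null(report$psych)) {
    wr_csv(report$psych$scores, "psych_scores.csv")
    wr_csv(report$psych$regression$coefficients, "psych_regression.csv")
    wr_csv(report$psych$partial, "psych_partial_correlations.csv")
    wr_csv(report$psych$ancova$between, "psych_ancova_between.csv")
    wr_csv(report$psych$ancova$within, "psych_ancova_within.csv")
    if (!is.null(report$psych$questionnaires))
      wr_csv(report$psych$questionnaires, "questionnaire_associations.csv")
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(c(files, file.path(out_dir, "run_log.txt")))
}

#' @export
print.info_report <- function(x, ...) {
  cat("Information-seeking analysis report\n")
  print(x$exclusions)
  cat("\nFixed effects (full model):\n")
  print(x$fixed_effects, row.names = FALSE, digits = 3)
  cat("\nBest model by BIC:", x$model_comparison$best_bic, "\n")
  cat("Dominance tiers (%):\n")
  print(x$profile$by_tier, row.names = FALSE, digits = 3)
  if (!is.null(x$stability)) {
    cat("\n"); print(x$stability$permutation)
    cat("ICC per motive:\n"); print(x$stability$icc, row.names = FALSE,
                                    digits = 3)
  }
  invisible(x)
}
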