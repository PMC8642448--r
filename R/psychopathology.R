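#' Score participants on the three transdiagnostic dimensions
#'
#' Each questionnaire item is z-scored across participants (sample SD), the
#' z-scores are multiplied by the item's published factor weight on each of
#' the three dimensions (Anxious-Depression, Social-Withdrawal,
#' Compulsive-Behaviour and Intrusive Thought), and a participant's
#' dimension score is the sum of the weighted items. The average of the
#' three dimension scores summarizes overall symptom load. Participants who
#' did not answer every scored item are flagged incomplete and should be
#' excluded from association analyses.
#'
#' @param questionnaire long data.frame: `participant_id`, `item_id`,
#'   `rating`.
#' @param factor_weights data.frame: `item_id`, `dim_AD`, `dim_SW`,
#'   `dim_CIT` (see [load_factor_weights()]).
#' @param zscore z-score items first (default TRUE; FALSE reproduces the
#'   raw-score sensitivity analysis).
#' @return data.frame: `participant_id`, `score_AD`, `score_SW`,
#'   `score_CIT`, `average_score`, `complete`.
#' @export
score_dimensions <- function(questionnaire, factor_weights, zscore = TRUE) {
  unmapped <- setdiff(unique(questionnaire$item_id), factor_weights$item_id)
  if (length(unmapped))
    stop("questionnaire item(s) without factor weights: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  ids <- sort(unique(questionnaire$participant_id))
  if (length(ids) < 2L)
    stop("z-scoring needs >= 2 participants", call. = FALSE)
  items <- factor_weights$item_id
  # participants x items rating matrix
  R <- matrix(NA_real_, length(ids), length(items),
              dimnames = list(ids, items))
  R[cbind(match(questionnaire$participant_id, ids),
          match(questionnaire$item_id, items))] <- questionnaire$rating
  complete <- !apply(R, 1, anyNA)

  Z <- R
  if (zscore) {
    for (j in seq_along(items)) {
      v <- R[, j]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        warning("item ", items[j], " has zero variance; z-score set to 0",
                call. = FALSE)
        Z[, j] <- ifelse(is.na(v), NA_real_, 0)
      } else {
        Z[, j] <- (v - mean(v, na.rm = TRUE)) / s
      }
    }
  }
  W <- as.matrix(factor_weights[, c("dim_AD", "dim_SW", "dim_CIT")])
  Z0 <- Z; Z0[is.na(Z0)] <- 0          # incomplete rows are flagged anyway
  S <- Z0 %*% W
  out <- data.frame(participant_id = ids,
                    score_AD = S[, 1], score_SW = S[, 2], score_CIT = S[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$average_score <- rowMeans(S)
  out$complete <- unname(complete)
  out
}

# Shared assembly of the association design: complete scores merged with
# motive weights (averaged across timepoints if more than one is present)
# and demographics; gender dummy-coded with the most frequent level as
# reference.
association_frame <- function(scores, weights, demographics) {
  if ("timepoint" %in% names(weights) &&
      length(unique(weights$timepoint)) > 1L) {
    agg <- stats::aggregate(
      weights[c("beta_instrumental", "beta_hedonic", "beta_cognitive")],
      by = list(participant_id = weights$participant_id), FUN = mean)
    weights <- agg
  }
  df <- merge(scores[scores$complete, , drop = FALSE], weights,
              by = "participant_id")
  df <- merge(df, demographics[c("participant_id", "age", "gender")],
              by = "participant_id")
  if (nrow(df) < 8L)
    stop("too few complete participants for association analyses",
         call. = FALSE)
  glev <- names(sort(table(df$gender), decreasing = TRUE))
  if (length(glev) < 2L) {
    warning("fewer than 2 gender levels; gender collapsed to intercept",
            call. = FALSE)
    df$gender <- NULL
  } else {
    df$gender <- stats::relevel(factor(df$gender, levels = sort(glev)),
                                ref = glev[1])
  }
  df
}

association_formula_rhs <- function(df) {
  rhs <- c("beta_instrumental", "beta_hedonic", "beta_cognitive", "age")
  if ("gender" %in% names(df)) rhs <- c(rhs, "gender")
  rhs
}

#' Repeated-measures ANCOVA of dimension scores on motive weights
#'
#' Mixed analysis of covariance with psychopathology dimension (three
#' levels) as the within-subject factor and the three motive weights, age
#' and gender as covariates, using Type III sums of squares. The
#' between-subject stratum of this design is algebraically a regression on
#' each participant's mean score, so each covariate's main-effect F equals
#' the squared t of the same predictor in
#' [average_score_regression()]; dimension-by-covariate interactions come
#' from the within-subject stratum.
#'
#' @param scores data.frame from [score_dimensions()] (incomplete
#'   participants are dropped).
#' @param weights subject-weights data.frame; if two timepoints are present
#'   the weights are first averaged across timepoints.
#' @param demographics data.frame with `participant_id`, `age`, `gender`.
#' @return list with `between` (per-covariate F, df, p, partial eta
#'   squared), `within` (dimension main effect and interactions), `n`.
#' @export
ancova_dimensions <- function(scores, weights, demographics) {
  df <- association_frame(scores, weights, demographics)
  if (stats::var(c(as.matrix(df[c("score_AD", "score_SW", "score_CIT")])
                   - df$average_score)) == 0)
    stop("all three dimension scores identical per participant; ",
         "within-subject effects undefined", call. = FALSE)
  rhs <- association_formula_rhs(df)
  mform <- stats::as.formula(paste(
    "cbind(score_AD, score_SW, score_CIT) ~", paste(rhs, collapse = " + ")))
  mlm <- stats::lm(mform, data = df)
  idata <- data.frame(dimension = factor(c("AD", "SW", "CIT"),
                                         levels = c("AD", "SW", "CIT")))
  av <- car::Anova(mlm, idata = idata, idesign = ~dimension, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- as.data.frame(unclass(s$univariate.tests))
  names(ut) <- c("SS", "df_num", "SS_error", "df_den", "F", "p")
  ut$effect <- rownames(ut)
  ut$partial_eta_sq <- ut$SS / (ut$SS + ut$SS_error)
  rownames(ut) <- NULL
  is_within <- grepl("dimension", ut$effect)
  between <- ut[!is_within & ut$effect != "(Intercept)", ]
  within <- ut[is_within, ]
  list(between = between[, c("effect", "F", "df_num", "df_den", "p",
                             "partial_eta_sq")],
       within = within[, c("effect", "F", "df_num", "df_den", "p",
                           "partial_eta_sq")],
       n = nrow(df))
}

#' Regression of average psychopathology score on motive weights
#'
#' Ordinary least squares of the average dimension score on the three
#' motive weights plus age and gender, the simplified between-subject view
#' of [ancova_dimensions()].
#'
#' @inheritParams ancova_dimensions
#' @return list with `coefficients` (term, estimate, se, t, p), `n`,
#'   `r_squared`, and the fitted `lm` object.
#' @export
average_score_regression <- function(scores, weights, demographics) {
  df <- association_frame(scores, weights, demographics)
  rhs <- association_formula_rhs(df)
  fit <- stats::lm(stats::as.formula(
    paste("average_score ~", paste(rhs, collapse = " + "))), data = df)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient association design", call. = FALSE)
  co <- as.data.frame(stats::coef(summary(fit)))
  names(co) <- c("estimate", "se", "t", "p")
  co$term <- rownames(co); rownames(co) <- NULL
  list(coefficients = co[, c("term", "estimate", "se", "t", "p")],
       n = nrow(df), r_squared = summary(fit)$r.squared, fit = fit)
}

#' Partial correlations of each motive weight with mean symptom score
#'
#' Residual-on-residual Pearson correlations: each weight and the average
#' psychopathology score are first residualized on age and gender, then
#' correlated. Degrees of freedom are `n - 2 - q` where `q` is the number
#' of control columns (age plus gender dummies; `n - 4` with binary
#' gender).
#'
#' @inheritParams ancova_dimensions
#' @return data.frame with one row per motive: `r`, `df`, `p`.
#' @export
partial_correlations <- function(scores, weights, demographics) {
  df <- association_frame(scores, weights, demographics)
  ctrl <- if ("gender" %in% names(df)) "age + gender" else "age"
  res_y <- stats::resid(stats::lm(stats::as.formula(
    paste("average_score ~", ctrl)), data = df))
  q <- length(stats::coef(stats::lm(stats::as.formula(
    paste("average_score ~", ctrl)), data = df))) - 1L
  motives <- c(instrumental = "beta_instrumental", hedonic = "beta_hedonic",
               cognitive = "beta_cognitive")
  rows <- lapply(names(motives), function(m) {
    res_x <- stats::resid(stats::lm(stats::as.formula(
      paste(motives[[m]], "~", ctrl)), data = df))
    r <- stats::cor(res_x, res_y)
    dfree <- nrow(df) - 2L - q
    tstat <- r * sqrt(dfree / (1 - r^2))
    data.frame(motive = m, r = r, df = dfree,
               p = 2 * stats::pt(-abs(tstat), dfree),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Per-questionnaire associations with motive weights
#'
#' Relates each motive weight to each instrument's total score with a
#' simple linear model, Bonferroni-correcting the p-values across the nine
#' instruments within each motive (adjusted p = min(1, 9 p)).
#'
#' @param weights subject-weights data.frame (averaged across timepoints if
#'   needed).
#' @param questionnaire long questionnaire data.frame including an
#'   `instrument` column.
#' @param demographics demographics data.frame (currently carried for id
#'   alignment).
#' @return data.frame: `instrument`, `motive`, `estimate`, `p_raw`,
#'   `p_bonferroni`, `significant` (adjusted alpha 0.05).
#' @export
questionnaire_associations <- function(weights, questionnaire, demographics) {
  if (!"instrument" %in% names(questionnaire))
    stop("questionnaire table needs an 'instrument' column", call. = FALSE)
  totals <- stats::aggregate(rating ~ participant_id + instrument,
                             data = questionnaire, FUN = sum)
  if ("timepoint" %in% names(weights) &&
      length(unique(weights$timepoint)) > 1L) {
    weights <- stats::aggregate(
      weights[c("beta_instrumental", "beta_hedonic", "beta_cognitive")],
      by = list(participant_id = weights$participant_id), FUN = mean)
  }
  df <- merge(totals, weights, by = "participant_id")
  instruments <- unique(df$instrument)
  n_tests <- length(instruments)
  motives <- c(instrumental = "beta_instrumental", hedonic = "beta_hedonic",
               cognitive = "beta_cognitive")
  rows <- list()
  for (ins in instruments) {
    sub <- df[df$instrument == ins, , drop = FALSE]
    for (m in names(motives)) {
      fit <- stats::lm(sub$rating ~ sub[[motives[[m]]]])
      co <- stats::coef(summary(fit))
      p_raw <- co[2, 4]
      rows[[length(rows) + 1L]] <- data.frame(
        instrument = ins, motive = m, estimate = co[2, 1], p_raw = p_raw,
        p_bonferroni = min(1, n_tests * p_raw), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < 0.05
  row.names(out) <- NULL
  out
}
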