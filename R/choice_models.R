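#' Per-participant motive weights by ordinary least squares
#'
#' Fits, for each participant-by-timepoint block, a general linear model
#' predicting the numeric choice rating from the three utilities. Choice is
#' treated as numeric on the -3..+3 no-zero scale. Slopes are invariant to
#' within-participant centering, so raw utility columns are used and the
#' intercept absorbs the participant's mean.
#'
#' Participants whose design matrix is rank-deficient (e.g. a constant
#' utility column that slipped past exclusions) are flagged and omitted from
#' the result; their ids are attached as `attr(, "flagged")`.
#'
#' @param utilities utility table from [build_utilities()].
#' @return data.frame with one row per participant x timepoint: intercept,
#'   `beta_instrumental`, `beta_hedonic`, `beta_cognitive`, `r_squared`,
#'   `n_trials_used`.
#' @export
fit_subject_weights <- function(utilities) {
  blocks <- split(utilities,
                  interaction(utilities$participant_id, utilities$timepoint,
                              drop = TRUE))
  rows <- list(); flagged <- character(0)
  for (blk in blocks) {
    X <- cbind(1, blk$instrumental, blk$hedonic, blk$cognitive)
    y <- blk$choice
    if (nrow(X) < 4L || qr(X)$rank < 4L) {
      flagged <- c(flagged, paste0(blk$participant_id[1], "@", blk$timepoint[1]))
      next
    }
    fit <- stats::lm.fit(X, y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = blk$participant_id[1],
      timepoint = blk$timepoint[1],
      intercept = fit$coefficients[1],
      beta_instrumental = fit$coefficients[2],
      beta_hedonic = fit$coefficients[3],
      beta_cognitive = fit$coefficients[4],
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n_trials_used = nrow(X),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no participant block admitted a full-rank fit", call. = FALSE)
  row.names(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Candidate model specifications for the choice mixed model
#'
#' A specification names the fixed terms (drawn from the three utilities
#' plus the confidence rating); random structure is by-participant intercept
#' and slopes for every included term, plus a by-item random intercept.
#'
#' @param fixed_terms character subset of
#'   `c("instrumental", "hedonic", "cognitive", "confidence")`.
#' @param label optional stable label; defaults to the terms joined by `+`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(fixed_terms, label = NULL) {
  allowed <- c("instrumental", "hedonic", "cognitive", "confidence")
  fixed_terms <- as.character(fixed_terms)
  if (!length(fixed_terms) || !all(fixed_terms %in% allowed))
    stop("fixed_terms must be a nonempty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  fixed_terms <- allowed[allowed %in% fixed_terms]   # canonical order
  out <- list(fixed_terms = fixed_terms,
              label = if (is.null(label)) paste(fixed_terms, collapse = "+")
                      else label)
  class(out) <- "model_spec"
  out
}

#' Enumerate the candidate model space
#'
#' The full three-utility model plus its six strict-subset utility models
#' (7 specs); with `include_confidence`, also confidence alone and
#' confidence joined with every nonempty utility subset (8 more; 15 total).
#'
#' @param include_confidence include confidence-containing specs.
#' @return list of `model_spec` objects with stable labels; the full
#'   three-utility model carries the label `"full"`.
#' @export
enumerate_model_space <- function(include_confidence = FALSE) {
  utilities <- c("instrumental", "hedonic", "cognitive")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(utilities, k, simplify = FALSE)), recursive = FALSE)
  specs <- lapply(subsets, function(s)
    model_spec(s, label = if (length(s) == 3) "full" else NULL))
  if (include_confidence) {
    conf_sets <- c(list(character(0)), subsets)
    specs <- c(specs, lapply(conf_sets, function(s)
      model_spec(c(s, "confidence"),
                 label = if (length(s) == 3) "confidence+full" else NULL)))
  }
  specs
}

#' Fit the choice mixed-effects model
#'
#' Linear mixed model of the numeric choice rating on the within-participant
#' centered fixed terms of `spec`, with by-participant random intercept and
#' slopes for every fixed term and a by-item random intercept. The
#' by-participant random effects use a diagonal (independent) covariance by
#' default, which is markedly more robust to convergence failure on
#' 40-trial subjects; an unstructured covariance is available.
#'
#' Estimation is by maximum likelihood by default because fits are compared
#' across specifications differing in fixed effects; restricted ML can be
#' requested for reporting the final model's estimates. Degrees of freedom
#' for the fixed-effect t-tests use the Satterthwaite approximation.
#'
#' @param utilities utility table; centered `*_c` columns are created if
#'   absent.
#' @param spec a [model_spec()].
#' @param REML use restricted maximum likelihood (default FALSE).
#' @param random_cov `"diagonal"` or `"unstructured"` by-participant
#'   covariance.
#' @param ddf `"satterthwaite"` (via lmerTest) or `"none"` (faster; no
#'   t-test df/p).
#' @return an object of class `model_fit`: the spec, a `fixed_effects`
#'   coefficient table, `random_variances`, `log_likelihood`, `aic`, `bic`,
#'   `k`, `n_obs`, `converged`, `reductions` (any random-structure
#'   simplification applied), and the underlying `fit` object.
#' @export
fit_mixed_model <- function(utilities, spec = model_spec(c("instrumental",
                                                           "hedonic",
                                                           "cognitive"),
                                                         label = "full"),
                            REML = FALSE,
                            random_cov = c("diagonal", "unstructured"),
                            ddf = c("satterthwaite", "none")) {
  random_cov <- match.arg(random_cov)
  ddf <- match.arg(ddf)
  stopifnot(inherits(spec, "model_spec"))
  if (length(unique(utilities$participant_id)) < 2L)
    stop("mixed model needs >= 2 participants", call. = FALSE)
  if (length(unique(utilities$item_id)) < 2L)
    stop("mixed model needs >= 2 items (item random intercept inestimable)",
         call. = FALSE)
  terms_c <- paste0(spec$fixed_terms, "_c")
  if (!all(terms_c %in% names(utilities)))
    utilities <- center_within_participant(utilities,
                                           columns = spec$fixed_terms)
  if ("confidence" %in% spec$fixed_terms &&
      anyNA(utilities$confidence_c))
    stop("confidence rating missing; cannot fit a confidence spec",
         call. = FALSE)

  fe <- paste(terms_c, collapse = " + ")
  re_sep <- if (random_cov == "diagonal") "||" else "|"
  form <- stats::as.formula(paste0(
    "choice ~ ", fe,
    " + (1 + ", fe, " ", re_sep, " participant_id) + (1 | item_id)"))

  fitter <- if (ddf == "satterthwaite") lmerTest::lmer else lme4::lmer
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    fitter(form, data = utilities, REML = REML,
           control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- !any(grepl("failed to converge", c(warn_msgs, conv_msgs),
                          ignore.case = TRUE))

  co <- as.data.frame(stats::coef(summary(fit)))
  if (ddf == "none") {
    co$df <- NA_real_
    co$p <- NA_real_
    names(co) <- c("estimate", "se", "t", "df", "p")
  } else {
    co <- co[, c("Estimate", "Std. Error", "t value", "df", "Pr(>|t|)")]
    names(co) <- c("estimate", "se", "t", "df", "p")
  }
  co$term <- sub("_c$", "", rownames(co))
  rownames(co) <- NULL

  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n_obs <- stats::nobs(fit)
  aic <- 2 * k - 2 * as.numeric(ll)
  bic <- k * log(n_obs) - 2 * as.numeric(ll)
  # self-check against the generic extractors
  stopifnot(isTRUE(all.equal(aic, stats::AIC(fit), tolerance = 1e-8)),
            isTRUE(all.equal(bic, stats::BIC(fit), tolerance = 1e-8)))

  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(spec = spec, fixed_effects = co, random_variances = vc,
              log_likelihood = as.numeric(ll), aic = aic, bic = bic,
              k = k, n_obs = n_obs, converged = converged,
              reml = REML, random_cov = random_cov, ddf_method = ddf,
              reductions = character(0), fit = fit)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Choice mixed model [", x$spec$label, "]",
      if (!x$converged) " (DID NOT CONVERGE)", "\n", sep = "")
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  cat(sprintf("logLik %.2f  k %d  n_obs %d  AIC %.1f  BIC %.1f\n",
              x$log_likelihood, x$k, x$n_obs, x$aic, x$bic))
  invisible(x)
}

#' Rank candidate model fits by information criteria
#'
#' Converged fits are ranked by BIC and, separately, by AIC (ascending,
#' ties going to the smaller parameter count). Non-converged fits are
#' listed apart with a warning rather than ranked. All fits must share the
#' same observation set.
#'
#' @param fits list of `model_fit` objects.
#' @return an object of class `model_comparison`: a `table` data.frame
#'   (label, k, logLik, AIC, BIC, delta_AIC, delta_BIC, converged,
#'   rank_bic, rank_aic) and the labels of the BIC- and AIC-best specs.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "model_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L)
    stop("fits computed on differing observation counts; refusing to rank",
         call. = FALSE)
  tab <- data.frame(
    label = vapply(fits, function(f) f$spec$label, ""),
    k = vapply(fits, `[[`, 0, "k"),
    logLik = vapply(fits, `[[`, 0, "log_likelihood"),
    AIC = vapply(fits, `[[`, 0, "aic"),
    BIC = vapply(fits, `[[`, 0, "bic"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  conv <- tab[tab$converged, , drop = FALSE]
  if (!nrow(conv)) stop("no converged fits to rank", call. = FALSE)
  if (any(!tab$converged))
    warning("excluded from ranking (non-converged): ",
            paste(tab$label[!tab$converged], collapse = ", "), call. = FALSE)
  tab$delta_AIC <- tab$AIC - min(conv$AIC)
  tab$delta_BIC <- tab$BIC - min(conv$BIC)
  rk <- function(crit) {
    r <- rep(NA_integer_, nrow(tab))
    ord <- order(tab[[crit]][tab$converged], tab$k[tab$converged])
    r[which(tab$converged)[ord]] <- seq_len(nrow(conv))
    r
  }
  tab$rank_bic <- rk("BIC")
  tab$rank_aic <- rk("AIC")
  out <- list(table = tab,
              best_bic = tab$label[which(tab$rank_bic == 1L)],
              best_aic = tab$label[which(tab$rank_aic == 1L)])
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- x$table[order(x$table$rank_bic, na.last = TRUE), ]
  print(tab, row.names = FALSE, digits = 4)
  cat("best by BIC:", x$best_bic, " best by AIC:", x$best_aic, "\n")
  invisible(x)
}
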