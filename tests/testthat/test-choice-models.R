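test_that("per-subject OLS interpolates noise-free linear data exactly", {
  ut <- make_linear_utilities(c(0.5, 0.2, 0.1), intercepts = 1, k = 12)
  sw <- fit_subject_weights(ut)
  expect_equal(sw$intercept, 1, tolerance = 1e-12)
  expect_equal(sw$beta_instrumental, 0.5, tolerance = 1e-12)
  expect_equal(sw$beta_hedonic, 0.2, tolerance = 1e-12)
  expect_equal(sw$beta_cognitive, 0.1, tolerance = 1e-12)
  expect_equal(sw$r_squared, 1, tolerance = 1e-12)
  expect_equal(sw$n_trials_used, 12)
})

test_that("per-subject OLS matches the normal-equations oracle", {
  set.seed(13)
  for (i in 1:5) {
    ut <- make_linear_utilities(rnorm(3), k = 15, seed = i, noise_sd = 1)
    sw <- fit_subject_weights(ut)
    X <- cbind(1, ut$instrumental, ut$hedonic, ut$cognitive)
    expect_equal(unname(c(sw$intercept, sw$beta_instrumental, sw$beta_hedonic,
                          sw$beta_cognitive)),
                 unname(normal_equations(X, ut$choice)), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are flagged rather than fitted", {
  ut <- make_linear_utilities(c(0.5, 0.2, 0.1, 0.3, 0.3, 0.3), k = 10)
  ut$cognitive[ut$participant_id == "P01"] <- 2   # constant column
  sw <- fit_subject_weights(ut)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "flagged"), "P01@T1")
})

test_that("the candidate model space enumerates 7 or 15 stable specs", {
  sp7 <- enumerate_model_space(FALSE)
  expect_length(sp7, 7)
  labels7 <- vapply(sp7, function(s) s$label, "")
  expect_equal(sum(labels7 == "full"), 1)
  expect_false(any(grepl("confidence", labels7)))
  sp15 <- enumerate_model_space(TRUE)
  expect_length(sp15, 15)
  labels15 <- vapply(sp15, function(s) s$label, "")
  expect_equal(anyDuplicated(labels15), 0)
  expect_equal(sum(grepl("confidence", labels15)), 8)
  expect_true("confidence" %in% labels15)          # confidence-only spec
  expect_error(model_spec(character(0)))
  expect_error(model_spec("certainty"))
})

test_that("mixed-model information criteria are recomputable from stored parts", {
  b <- generate_dataset(generator_config(n_subjects = 25, n_trials = 20,
                                         timepoints = 1, seed = 41))
  ut <- center_within_participant(build_utilities(b$trials_t1))
  f <- suppressMessages(fit_mixed_model(ut, ddf = "satterthwaite"))
  expect_equal(f$aic, 2 * f$k - 2 * f$log_likelihood, tolerance = 1e-8)
  expect_equal(f$bic, f$k * log(f$n_obs) - 2 * f$log_likelihood,
               tolerance = 1e-8)
  expect_equal(f$n_obs, nrow(ut))
  fe <- f$fixed_effects
  expect_setequal(fe$term, c("(Intercept)", "instrumental", "hedonic",
                             "cognitive"))
  expect_true(all(is.finite(fe$df)) && all(fe$df > 0))  # Satterthwaite df
})

test_that("degenerate variance data reduce the mixed model to pooled OLS", {
  # one fixed term, zero residual and zero between-unit variance
  set.seed(3)
  n <- 12; k <- 10
  u <- rnorm(n * k)
  ut <- data.frame(participant_id = rep(sprintf("P%02d", 1:n), each = k),
                   timepoint = "T1",
                   item_id = rep(sprintf("it%02d", 1:k), n),
                   choice = 0.4 * u, instrumental = u, hedonic = 0,
                   cognitive = 0, confidence = 0)
  f <- suppressMessages(fit_mixed_model(ut, model_spec("instrumental"),
                                        ddf = "none"))
  pooled <- coef(lm(choice ~ instrumental_c,
                    data = center_within_participant(ut)))
  est <- f$fixed_effects$estimate[f$fixed_effects$term == "instrumental"]
  expect_equal(est, unname(pooled["instrumental_c"]), tolerance = 1e-6)
})

test_that("a single item makes the item random intercept inestimable", {
  ut <- make_linear_utilities(c(0.5, 0.2, 0.1, 0.3, 0.2, 0.1), k = 10)
  ut$item_id <- "only_item"
  expect_error(suppressMessages(fit_mixed_model(ut)), ">= 2 items")
  one <- make_linear_utilities(c(0.5, 0.2, 0.1), k = 10)
  expect_error(suppressMessages(fit_mixed_model(one)), ">= 2 participants")
})

test_that("mean per-subject betas approach the fixed effects when slope variance is small", {
  cfg <- generator_config(n_subjects = 120, n_trials = 40, timepoints = 1,
                          population_cov_weights = diag(rep(1e-4, 3)),
                          noise_sd = 0.6, seed = 19)
  b <- generate_dataset(cfg)
  ut <- center_within_participant(build_utilities(b$trials_t1))
  f <- suppressMessages(fit_mixed_model(ut, ddf = "none"))
  sw <- fit_subject_weights(ut)
  fe <- f$fixed_effects
  expect_lt(abs(mean(sw$beta_instrumental) -
                  fe$estimate[fe$term == "instrumental"]), 0.02)
  expect_lt(abs(mean(sw$beta_hedonic) -
                  fe$estimate[fe$term == "hedonic"]), 0.02)
  expect_lt(abs(mean(sw$beta_cognitive) -
                  fe$estimate[fe$term == "cognitive"]), 0.02)
})

fake_fit <- function(label, logLik, k, n_obs, converged = TRUE) {
  structure(list(spec = model_spec("instrumental", label = label),
                 log_likelihood = logLik, k = k, n_obs = n_obs,
                 aic = 2 * k - 2 * logLik,
                 bic = k * log(n_obs) - 2 * logLik,
                 converged = converged),
            class = "model_fit")
}

test_that("model ranking follows the information-criterion closed forms", {
  f <- fake_fit("a", logLik = -100, k = 5, n_obs = 100)
  expect_equal(f$bic, 5 * log(100) + 200, tolerance = 1e-9)
  expect_equal(f$bic, 223.0259, tolerance = 1e-4)
  g <- fake_fit("b", logLik = -100, k = 4, n_obs = 100)
  cmp <- compare_models(list(f, g))
  expect_equal(cmp$best_bic, "b")     # equal logLik: smaller k wins
  expect_equal(cmp$best_aic, "b")
  expect_equal(cmp$table$delta_BIC[cmp$table$label == "a"], log(100),
               tolerance = 1e-9)
})

test_that("non-converged fits are set aside and unequal n_obs refuses to rank", {
  f <- fake_fit("good", -100, 5, 100)
  bad <- fake_fit("bad", -90, 5, 100, converged = FALSE)
  expect_warning(cmp <- compare_models(list(f, bad)), "non-converged")
  expect_equal(cmp$best_bic, "good")
  expect_true(is.na(cmp$table$rank_bic[cmp$table$label == "bad"]))
  other_n <- fake_fit("other", -100, 5, 90)
  expect_error(compare_models(list(f, other_n)), "differing observation")
})
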