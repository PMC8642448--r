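make_fw <- function(items, dims, w) {
  fw <- data.frame(item_id = items, instrument = "OCI-R",
                   dim_AD = 0, dim_SW = 0, dim_CIT = 0)
  for (i in seq_along(items)) fw[i, paste0("dim_", dims[i])] <- w[i]
  fw
}

test_that("dimension scoring matches hand arithmetic on a two-person example", {
  q <- data.frame(participant_id = c("a", "b"), item_id = "q1",
                  rating = c(1, 3))
  fw <- make_fw("q1", "AD", 0.5)
  sc <- score_dimensions(q, fw)
  z <- (c(1, 3) - 2) / sd(c(1, 3))        # sample SD sqrt(2)
  expect_equal(sc$score_AD, 0.5 * z)
  expect_equal(sc$score_AD, c(-0.3536, 0.3536), tolerance = 1e-3)
  expect_equal(sc$score_SW, c(0, 0))
  expect_equal(sc$average_score, sc$score_AD / 3)
  expect_true(all(sc$complete))
})

test_that("scoring is linear in the weights and zero weights give zero scores", {
  set.seed(4)
  items <- sprintf("q%02d", 1:6)
  q <- expand.grid(participant_id = sprintf("P%d", 1:10), item_id = items,
                   stringsAsFactors = FALSE)
  q$rating <- sample(0:4, nrow(q), TRUE)
  fw <- make_fw(items, rep(c("AD", "SW", "CIT"), 2), runif(6))
  s1 <- score_dimensions(q, fw)
  fw2 <- fw; fw2[paste0("dim_", c("AD", "SW", "CIT"))] <-
    2 * fw2[paste0("dim_", c("AD", "SW", "CIT"))]
  s2 <- score_dimensions(q, fw2)
  expect_equal(s2$score_AD, 2 * s1$score_AD)
  expect_equal(s2$average_score, 2 * s1$average_score)
  fw0 <- fw; fw0[paste0("dim_", c("AD", "SW", "CIT"))] <- 0
  s0 <- score_dimensions(q, fw0)
  expect_true(all(s0$average_score == 0))
})

test_that("z-scored item columns have mean 0 and sample SD 1", {
  set.seed(6)
  items <- sprintf("q%02d", 1:4)
  q <- expand.grid(participant_id = sprintf("P%d", 1:20), item_id = items,
                   stringsAsFactors = FALSE)
  q$rating <- sample(0:4, nrow(q), TRUE)
  fw <- make_fw(items, rep("AD", 4), rep(1, 4))
  # single-item dimensions expose the z-scores directly
  for (it in items) {
    fw1 <- make_fw(it, "AD", 1)
    sc <- score_dimensions(q[q$item_id == it, ], fw1)
    expect_equal(mean(sc$score_AD), 0, tolerance = 1e-12)
    expect_equal(sd(sc$score_AD), 1, tolerance = 1e-12)
  }
})

test_that("degenerate items and unmapped items are handled as declared", {
  q <- data.frame(participant_id = rep(c("a", "b"), 2),
                  item_id = rep(c("q1", "q2"), each = 2),
                  rating = c(2, 2, 1, 4))              # q1 constant
  fw <- make_fw(c("q1", "q2"), c("AD", "AD"), c(1, 1))
  expect_warning(sc <- score_dimensions(q, fw), "zero variance")
  expect_equal(suppressWarnings(score_dimensions(q, fw))$score_AD,
               (c(1, 4) - 2.5) / sd(c(1, 4)))
  expect_error(score_dimensions(q, fw[1, ]), "without factor weights")
  # missing an item flags the participant incomplete
  q2 <- q[-1, ]
  expect_warning(sc2 <- score_dimensions(q2, fw), "zero variance")
  expect_false(sc2$complete[sc2$participant_id == "a"])
})

# A small association cohort with a known cognitive-weight coupling.
make_cohort <- function(n = 60, gamma = -1, noise = 0.3, seed = 31) {
  set.seed(seed)
  w <- make_weights(rnorm(3 * n, sd = 0.3))
  demo <- make_participants(w$participant_id,
                            age = round(runif(n, 20, 60)),
                            gender = sample(c("female", "male"), n, TRUE))
  base <- gamma * w$beta_cognitive + 0.02 * demo$age +
    0.4 * (demo$gender == "female") + rnorm(n, 0, noise)
  scores <- data.frame(participant_id = w$participant_id,
                       score_AD = base + rnorm(n, 0, 0.2),
                       score_SW = base + rnorm(n, 0, 0.2),
                       score_CIT = base + rnorm(n, 0, 0.2))
  scores$average_score <- rowMeans(scores[2:4])
  scores$complete <- TRUE
  list(weights = w, demo = demo, scores = scores)
}

test_that("ANCOVA covariate main effects equal squared regression t-values", {
  co <- make_cohort()
  anc <- ancova_dimensions(co$scores, co$weights, co$demo)
  reg <- average_score_regression(co$scores, co$weights, co$demo)
  for (term in c("beta_instrumental", "beta_hedonic", "beta_cognitive",
                 "age")) {
    Fa <- anc$between$F[anc$between$effect == term]
    tr <- reg$coefficients$t[reg$coefficients$term == term]
    expect_equal(Fa, tr^2, tolerance = 1e-8)
    expect_equal(anc$between$p[anc$between$effect == term],
                 reg$coefficients$p[reg$coefficients$term == term],
                 tolerance = 1e-8)
  }
  expect_true(all(anc$between$partial_eta_sq >= 0 &
                    anc$between$partial_eta_sq <= 1))
  expect_true(any(grepl("dimension", anc$within$effect)))
})

test_that("identical dimension scores leave the within-subject stratum undefined", {
  co <- make_cohort()
  flat <- co$scores
  flat$score_SW <- flat$score_AD
  flat$score_CIT <- flat$score_AD
  flat$average_score <- flat$score_AD
  expect_error(ancova_dimensions(flat, co$weights, co$demo),
               "identical per participant")
})

test_that("planted zero-noise relations are recovered exactly by the regression", {
  co <- make_cohort(noise = 0)
  sc <- co$scores
  sc$score_AD <- sc$score_SW <- sc$score_CIT <- sc$average_score <-
    -1 * co$weights$beta_cognitive + 0.02 * co$demo$age +
    0.4 * (co$demo$gender == "female")
  # zero residual noise: lm warns about an essentially perfect fit
  reg <- suppressWarnings(average_score_regression(sc, co$weights, co$demo))
  cf <- reg$coefficients
  expect_equal(cf$estimate[cf$term == "beta_cognitive"], -1, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "beta_instrumental"], 0,
               tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "age"], 0.02, tolerance = 1e-10)
})

test_that("regression coefficients match the normal-equations oracle", {
  co <- make_cohort(seed = 8)
  reg <- average_score_regression(co$scores, co$weights, co$demo)
  df <- merge(merge(co$scores, co$weights, by = "participant_id"),
              co$demo, by = "participant_id")
  ref_level <- names(sort(table(df$gender), decreasing = TRUE))[1]
  X <- cbind(1, df$beta_instrumental, df$beta_hedonic, df$beta_cognitive,
             df$age, as.numeric(df$gender != ref_level))
  beta <- normal_equations(X, df$average_score)
  got <- reg$coefficients$estimate
  expect_equal(sort(got), sort(unname(beta)), tolerance = 1e-8)
})

test_that("partial correlations match the inverse-correlation-matrix oracle", {
  co <- make_cohort(seed = 12)
  pc <- partial_correlations(co$scores, co$weights, co$demo)
  df <- merge(merge(co$scores, co$weights, by = "participant_id"),
              co$demo, by = "participant_id")
  df$female <- as.numeric(df$gender == "female")
  for (m in c("instrumental", "hedonic", "cognitive")) {
    M <- as.matrix(df[, c(paste0("beta_", m), "average_score", "age",
                          "female")])
    P <- solve(cor(M))    # precision-matrix route to the partial correlation
    r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(pc$r[pc$motive == m], r_oracle, tolerance = 1e-8)
  }
  expect_equal(pc$df, rep(nrow(df) - 4, 3))
})

test_that("constant controls reduce the partial correlation to plain Pearson", {
  co <- make_cohort(seed = 14)
  co$demo$age <- 40
  co$demo$gender <- "female"
  expect_warning(pc <- partial_correlations(co$scores, co$weights, co$demo),
                 "gender collapsed")
  df <- merge(co$scores, co$weights, by = "participant_id")
  expect_equal(pc$r[pc$motive == "cognitive"],
               cor(df$beta_cognitive, df$average_score), tolerance = 1e-10)
})

test_that("perfectly linear weight-score relations give partial r of 1", {
  co <- make_cohort(seed = 15)
  sc <- co$scores
  sc$average_score <- co$weights$beta_cognitive
  pc <- partial_correlations(sc, co$weights, co$demo)
  expect_equal(pc$r[pc$motive == "cognitive"], 1, tolerance = 1e-8)
})

test_that("per-questionnaire p-values are Bonferroni-corrected across instruments", {
  set.seed(16)
  n <- 40
  w <- make_weights(rnorm(3 * n, sd = 0.3))
  demo <- make_participants(w$participant_id)
  instruments <- sprintf("INST%d", 1:9)
  q <- expand.grid(participant_id = w$participant_id,
                   item_id = sprintf("q%02d", 1:18),
                   stringsAsFactors = FALSE)
  q$instrument <- instruments[(match(q$item_id, sprintf("q%02d", 1:18)) - 1)
                              %% 9 + 1]
  q$rating <- sample(0:4, nrow(q), TRUE)
  tab <- questionnaire_associations(w, q, demo)
  expect_equal(nrow(tab), 9 * 3)
  expect_equal(tab$p_bonferroni, pmin(1, 9 * tab$p_raw))
  expect_true(all(tab$p_bonferroni <= 1))
  expect_equal(tab$significant, tab$p_bonferroni < 0.05)
})

test_that("weights at two timepoints are averaged before association analyses", {
  co <- make_cohort(seed = 18)
  w1 <- co$weights
  w2 <- co$weights
  w2$timepoint <- "T2"
  for (col in c("beta_instrumental", "beta_hedonic", "beta_cognitive"))
    w2[[col]] <- w2[[col]] + 0.2
  both <- rbind(w1, w2)
  reg_avg <- average_score_regression(co$scores, both, co$demo)
  manual <- w1
  for (col in c("beta_instrumental", "beta_hedonic", "beta_cognitive"))
    manual[[col]] <- manual[[col]] + 0.1
  reg_manual <- average_score_regression(co$scores, manual, co$demo)
  expect_equal(reg_avg$coefficients$estimate[-1],
               reg_manual$coefficients$estimate[-1], tolerance = 1e-10)
})
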