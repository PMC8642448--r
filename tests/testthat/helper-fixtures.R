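# Shared fixtures, built in code at test time.

# Subject-weights table from a matrix/vector of beta triples.
make_weights <- function(betas, ids = NULL, timepoint = "T1") {
  b <- matrix(betas, ncol = 3, byrow = TRUE)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nrow(b)))
  data.frame(participant_id = ids, timepoint = timepoint,
             beta_instrumental = b[, 1], beta_hedonic = b[, 2],
             beta_cognitive = b[, 3], intercept = 0,
             r_squared = NA_real_, n_trials_used = 40L,
             stringsAsFactors = FALSE)
}

# Minimal well-formed trials table (n participants x k items, one timepoint).
make_trials <- function(n = 3, k = 6, seed = 42) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("P%02d", seq_len(n)),
                   item_id = sprintf("it%02d", seq_len(k)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$timepoint <- "T1"
  g$domain <- "self-traits"
  g$valence <- rep(c("positive", "negative"), length.out = nrow(g))
  g$choice <- sample(c(-3:-1, 1:3), nrow(g), replace = TRUE)
  for (col in c("usefulness", "feel_know", "feel_not_know", "think_freq",
                "expectation", "confidence"))
    g[[col]] <- sample(-3:3, nrow(g), replace = TRUE)
  g
}

make_participants <- function(ids, age = 35, gender = "female", fails = 0L) {
  data.frame(participant_id = ids,
             age = rep_len(age, length(ids)),
             gender = rep_len(gender, length(ids)),
             attention_failures = as.integer(rep_len(fails, length(ids))),
             stringsAsFactors = FALSE)
}

# Continuous (noise-free unless noise_sd > 0) utility table with known
# per-subject weights: choice = intercept + B %*% (I, H, C).
make_linear_utilities <- function(B, intercepts = NULL, k = 12, seed = 9,
                                  noise_sd = 0) {
  set.seed(seed)
  B <- matrix(B, ncol = 3, byrow = TRUE)
  n <- nrow(B)
  if (is.null(intercepts)) intercepts <- rep(0, n)
  out <- lapply(seq_len(n), function(i) {
    u <- matrix(stats::rnorm(3 * k), k, 3)
    data.frame(participant_id = sprintf("P%02d", i), timepoint = "T1",
               item_id = sprintf("it%02d", seq_len(k)),
               choice = intercepts[i] + as.numeric(u %*% B[i, ]) +
                 stats::rnorm(k, 0, noise_sd),
               instrumental = u[, 1], hedonic = u[, 2], cognitive = u[, 3],
               confidence = stats::rnorm(k), expectation_valenced = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Normal-equations solution (X'X)^{-1} X'y, the brute-force OLS oracle.
normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
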