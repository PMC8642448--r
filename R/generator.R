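#' Configuration for the synthetic information-seeking data generator
#'
#' Builds a validated configuration object for [generate_dataset()]. The
#' generative model mirrors the structure the estimation pipeline assumes:
#' each participant carries a latent triple of motive weights (instrumental,
#' hedonic, cognitive) drawn from a multivariate normal population, latent
#' utility ratings are drawn with a configurable correlation structure and
#' discretized to the task's Likert scales, and the choice rating is a noisy
#' linear function of the utilities discretized to the six-point no-zero
#' scale.
#'
#' Default population mean weights sit near typical self-trait fixed effects
#' (about 0.11 / 0.12 / 0.09) so synthetic cohorts resemble the regime the
#' estimators are used in; every value is overridable.
#'
#' @param n_subjects number of participants (>= 2).
#' @param n_trials number of stimuli rated per participant per timepoint
#'   (>= 4, the minimum for a four-parameter per-subject fit).
#' @param population_mean_weights length-3 numeric: population means of the
#'   instrumental, hedonic and cognitive weights.
#' @param population_cov_weights 3x3 symmetric positive semi-definite
#'   covariance of the per-subject weights.
#' @param intercept_mean,intercept_sd mean and SD of the per-subject choice
#'   intercept (choice-scale units).
#' @param item_effect_sd SD of the per-item (stimulus) intercept.
#' @param noise_sd SD of the trial-level residual on the latent choice.
#' @param rating_corr 3x3 correlation of the latent utility ratings within a
#'   trial (instrumental, hedonic, cognitive).
#' @param rating_sd SD of each latent utility rating before discretization.
#' @param stability_rho autocorrelation in [-1, 1] of the per-subject weights
#'   (and intercepts) between the two timepoints.
#' @param psych_coupling slope of the latent psychopathology composite on the
#'   cognitive weight (negative values mean cognitive-motivated seekers
#'   report fewer symptoms).
#' @param psych_noise_sd SD of the subject-level psychopathology residual.
#' @param psych_age_slope,psych_gender_effect covariate terms entering the
#'   latent psychopathology composite (per year of age; additive shift for
#'   female participants).
#' @param n_items_per_dim questionnaire items loading on each of the three
#'   transdiagnostic dimensions.
#' @param item_noise_sd SD of item-level questionnaire noise.
#' @param attention_fail_rate probability a participant fails enough
#'   attention checks (2 of 5) to be excluded downstream.
#' @param timepoints 1 or 2; with 2 a second session with fresh stimuli is
#'   generated.
#' @param discretize if FALSE, ratings and choices are left continuous
#'   (useful for exact-recovery checks).
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return an object of class `info_generator_config` (a validated list).
#' @export
generator_config <- function(n_subjects = 80,
                             n_trials = 40,
                             population_mean_weights = c(instrumental = 0.114,
                                                         hedonic = 0.123,
                                                         cognitive = 0.091),
                             population_cov_weights = default_weight_cov(),
                             intercept_mean = 0.43,
                             intercept_sd = 1.0,
                             item_effect_sd = 0.3,
                             noise_sd = 1.0,
                             rating_corr = default_rating_corr(),
                             rating_sd = 1.5,
                             stability_rho = 0.65,
                             psych_coupling = -1.05,
                             psych_noise_sd = 1.0,
                             psych_age_slope = -0.01,
                             psych_gender_effect = 0.3,
                             n_items_per_dim = 10,
                             item_noise_sd = 0.8,
                             attention_fail_rate = 0,
                             timepoints = 2,
                             discretize = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    population_mean_weights = stats::setNames(as.numeric(population_mean_weights),
                                              c("instrumental", "hedonic", "cognitive")),
    population_cov_weights = as.matrix(population_cov_weights),
    intercept_mean = intercept_mean, intercept_sd = intercept_sd,
    item_effect_sd = item_effect_sd, noise_sd = noise_sd,
    rating_corr = as.matrix(rating_corr), rating_sd = rating_sd,
    stability_rho = stability_rho,
    psych_coupling = psych_coupling, psych_noise_sd = psych_noise_sd,
    psych_age_slope = psych_age_slope, psych_gender_effect = psych_gender_effect,
    n_items_per_dim = as.integer(n_items_per_dim), item_noise_sd = item_noise_sd,
    attention_fail_rate = attention_fail_rate,
    timepoints = as.integer(timepoints), discretize = isTRUE(discretize),
    seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "info_generator_config"
  cfg
}

default_weight_cov <- function(sds = c(0.25, 0.15, 0.25), corr = 0.2) {
  r <- matrix(corr, 3, 3); diag(r) <- 1
  diag(sds) %*% r %*% diag(sds)
}

default_rating_corr <- function(corr = 0.3) {
  r <- matrix(corr, 3, 3); diag(r) <- 1
  r
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 2L)
    stop("configuration error: n_subjects must be >= 2", call. = FALSE)
  if (cfg$n_trials < 4L)
    stop("configuration error: n_trials must be >= 4 (four-parameter per-subject fit)",
         call. = FALSE)
  check_psd <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("configuration error: ", what, " must be symmetric", call. = FALSE)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("configuration error: ", what, " must be positive semi-definite",
           call. = FALSE)
  }
  check_psd(cfg$population_cov_weights, "population_cov_weights")
  check_psd(cfg$rating_corr, "rating_corr")
  if (abs(cfg$stability_rho) > 1)
    stop("configuration error: stability_rho must lie in [-1, 1]", call. = FALSE)
  if (!cfg$timepoints %in% 1:2)
    stop("configuration error: timepoints must be 1 or 2", call. = FALSE)
  invisible(cfg)
}

#' Discretize a latent value onto a task Likert scale
#'
#' Maps continuous latent values to the nearest admissible level. The
#' seven-point scale is -3..+3; the six-point "no-zero" choice scale is
#' -3..-1, +1..+3. On the no-zero scale, latent values in (-0.5, 0.5) map to
#' -1 or +1 by sign; an exactly-zero latent maps to +1 (documented
#' tie-break).
#'
#' @param latent numeric vector of latent values.
#' @param scale `"7pt"` or `"6pt_nozero"`.
#' @return integer vector of ratings on the declared scale.
#' @examples
#' discretize_likert(2.7, "7pt")            # 3
#' discretize_likert(0.2, "6pt_nozero")     # 1
#' discretize_likert(-3.9, "7pt")           # -3
#' @export
discretize_likert <- function(latent, scale = c("7pt", "6pt_nozero")) {
  scale <- match.arg(scale)
  if (!is.numeric(latent)) stop("latent values must be numeric", call. = FALSE)
  if (scale == "7pt") {
    out <- pmin(3L, pmax(-3L, as.integer(round(latent))))
  } else {
    sgn <- ifelse(latent < 0, -1L, 1L)  # zero -> +1
    mag <- pmin(3L, pmax(1L, as.integer(round(abs(latent)))))
    out <- sgn * mag
  }
  out
}

#' Generate a synthetic information-seeking dataset
#'
#' Simulates a full study bundle: trial-level rating tables at one or two
#' timepoints, the latent per-subject motive weights that generated them, a
#' demographics table, a questionnaire response table and the item-by-
#' dimension factor-weight matrix used to score it.
#'
#' Per subject s, weights `w_s` are multivariate normal; per trial, latent
#' utility ratings are drawn with correlation `rating_corr`, the two "feel"
#' ratings are constructed so that their difference carries the hedonic
#' signal, and the latent choice is
#' `alpha_s + w_s . u + item_effect + noise`, discretized to the no-zero
#' scale. Timepoint-2 weights are mean-reverting:
#' `mu + rho (w - mu) + sqrt(1 - rho^2) * perturbation`, so `stability_rho`
#' maps interpretably onto test-retest agreement. The questionnaire is built
#' so each subject's latent composite equals
#' `psych_coupling * w_cognitive + covariate terms + noise`, spread over
#' items through the factor-weight matrix.
#'
#' @param config an `info_generator_config` from [generator_config()].
#' @return a list of class `info_bundle` with elements `trials_t1`,
#'   `trials_t2` (or NULL), `true_weights_t1`, `true_weights_t2` (or NULL),
#'   `participants`, `questionnaire`, `factor_weights`, and the `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "info_generator_config"))
    config <- do.call(generator_config, config)
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  mu <- config$population_mean_weights
  sig <- config$population_cov_weights

  w1 <- MASS::mvrnorm(n, mu = mu, Sigma = sig)
  if (n == 1L) w1 <- matrix(w1, nrow = 1)
  colnames(w1) <- names(mu)
  a1 <- stats::rnorm(n, config$intercept_mean, config$intercept_sd)

  true_w1 <- data.frame(participant_id = ids, timepoint = "T1",
                        beta_instrumental = w1[, 1], beta_hedonic = w1[, 2],
                        beta_cognitive = w1[, 3], intercept = a1,
                        stringsAsFactors = FALSE, row.names = NULL)

  trials_t1 <- simulate_timepoint(config, ids, w1, a1, timepoint = "T1")

  trials_t2 <- NULL; true_w2 <- NULL
  if (config$timepoints == 2L) {
    rho <- config$stability_rho
    pert <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = sig)
    if (n == 1L) pert <- matrix(pert, nrow = 1)
    w2 <- sweep(rho * sweep(w1, 2, mu), 2, mu, "+") + sqrt(1 - rho^2) * pert
    a2 <- config$intercept_mean + rho * (a1 - config$intercept_mean) +
      sqrt(1 - rho^2) * stats::rnorm(n, 0, config$intercept_sd)
    true_w2 <- data.frame(participant_id = ids, timepoint = "T2",
                          beta_instrumental = w2[, 1], beta_hedonic = w2[, 2],
                          beta_cognitive = w2[, 3], intercept = a2,
                          stringsAsFactors = FALSE, row.names = NULL)
    trials_t2 <- simulate_timepoint(config, ids, w2, a2, timepoint = "T2")
  }

  demo <- simulate_demographics(config, ids)
  psych <- simulate_questionnaire(config, ids, w1[, "cognitive"], demo)

  out <- list(trials_t1 = trials_t1, trials_t2 = trials_t2,
              true_weights_t1 = true_w1, true_weights_t2 = true_w2,
              participants = demo,
              questionnaire = psych$responses,
              factor_weights = psych$factor_weights,
              config = config)
  class(out) <- "info_bundle"
  out
}

# One session of trial-level data for all subjects. Latent utility triples
# are correlated across the three scales; the hedonic latent is split into
# the two "feel" ratings whose difference recovers it.
simulate_timepoint <- function(cfg, ids, w, alpha, timepoint) {
  n <- length(ids); k <- cfg$n_trials
  item_ids <- sprintf("%s_item%02d", tolower(timepoint), seq_len(k))
  valence <- rep(c("positive", "negative"), length.out = k)
  item_eff <- stats::rnorm(k, 0, cfg$item_effect_sd)

  nrow_tot <- n * k
  lat <- MASS::mvrnorm(nrow_tot, mu = c(0, 0, 0),
                       Sigma = cfg$rating_sd^2 * cfg$rating_corr)
  colnames(lat) <- c("instrumental", "hedonic", "cognitive")
  # baseline affect level shared by the two feel ratings
  feel_base <- stats::rnorm(nrow_tot, 0, cfg$rating_sd / 2)
  feel_know_lat <- feel_base + lat[, "hedonic"] / 2
  feel_not_lat <- feel_base - lat[, "hedonic"] / 2
  expectation_lat <- stats::rnorm(nrow_tot, 0, cfg$rating_sd)
  confidence_lat <- stats::rnorm(nrow_tot, 0, cfg$rating_sd)

  if (cfg$discretize) {
    usefulness <- discretize_likert(lat[, "instrumental"], "7pt")
    feel_know <- discretize_likert(feel_know_lat, "7pt")
    feel_not_know <- discretize_likert(feel_not_lat, "7pt")
    think_freq <- discretize_likert(lat[, "cognitive"], "7pt")
    expectation <- discretize_likert(expectation_lat, "7pt")
    confidence <- discretize_likert(confidence_lat, "7pt")
  } else {
    usefulness <- lat[, "instrumental"]
    feel_know <- feel_know_lat
    feel_not_know <- feel_not_lat
    think_freq <- lat[, "cognitive"]
    expectation <- expectation_lat
    confidence <- confidence_lat
  }

  subj_idx <- rep(seq_len(n), each = k)
  item_idx <- rep(seq_len(k), times = n)
  u_inst <- as.numeric(usefulness)
  u_hed <- as.numeric(feel_know) - as.numeric(feel_not_know)
  u_cog <- as.numeric(think_freq)
  eps <- if (cfg$noise_sd > 0) stats::rnorm(nrow_tot, 0, cfg$noise_sd) else 0
  c_star <- alpha[subj_idx] +
    w[subj_idx, 1] * u_inst + w[subj_idx, 2] * u_hed + w[subj_idx, 3] * u_cog +
    item_eff[item_idx] + eps
  choice <- if (cfg$discretize) discretize_likert(c_star, "6pt_nozero") else c_star

  data.frame(participant_id = ids[subj_idx], timepoint = timepoint,
             domain = "self-traits", item_id = item_ids[item_idx],
             valence = valence[item_idx],
             choice = choice, usefulness = usefulness,
             feel_know = feel_know, feel_not_know = feel_not_know,
             think_freq = think_freq, expectation = expectation,
             confidence = confidence,
             stringsAsFactors = FALSE, row.names = NULL)
}

simulate_demographics <- function(cfg, ids) {
  n <- length(ids)
  age <- round(pmin(70, pmax(18, stats::rnorm(n, 38, 9))))
  gender <- sample(c("female", "male", "other"), n, replace = TRUE,
                   prob = c(0.46, 0.52, 0.02))
  fails <- ifelse(stats::runif(n) < cfg$attention_fail_rate,
                  sample(2:5, n, replace = TRUE), 0L)
  data.frame(participant_id = ids, age = age, gender = gender,
             attention_failures = as.integer(fails),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Questionnaire battery: three latent dimension scores per subject, all
# loaded on a shared composite coupled to the cognitive weight; items are
# noisy reflections of their dimension's latent, discretized to a 0..4
# severity scale, and tagged with instrument labels (nine instruments).
simulate_questionnaire <- function(cfg, ids, w_cog, demo) {
  n <- length(ids)
  m <- cfg$n_items_per_dim
  dims <- c("AD", "SW", "CIT")
  instruments <- c("OCI-R", "SDS", "STAI", "AUDIT", "AES",
                   "EAT-26", "BIS-11", "Schizotypy", "LSAS")
  item_ids <- sprintf("q%02d", seq_len(3 * m))
  item_dim <- rep(dims, each = m)
  fw <- matrix(0, nrow = 3 * m, ncol = 3,
               dimnames = list(item_ids, paste0("dim_", dims)))
  wts <- stats::runif(3 * m, 0.3, 0.9)
  for (d in 1:3) fw[item_dim == dims[d], d] <- wts[item_dim == dims[d]]
  factor_weights <- data.frame(item_id = item_ids,
                               instrument = rep(instruments, length.out = 3 * m),
                               fw, stringsAsFactors = FALSE, row.names = NULL)

  is_female <- as.numeric(demo$gender == "female")
  composite <- cfg$psych_coupling * w_cog +
    cfg$psych_age_slope * (demo$age - mean(demo$age)) +
    cfg$psych_gender_effect * is_female +
    stats::rnorm(n, 0, cfg$psych_noise_sd)
  # each dimension tracks the composite plus its own variation
  dim_lat <- composite + matrix(stats::rnorm(n * 3, 0, 0.5), n, 3)

  resp <- expand.grid(participant_id = ids, item_id = item_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d_idx <- match(item_dim[match(resp$item_id, item_ids)], dims)
  s_idx <- match(resp$participant_id, ids)
  latent <- dim_lat[cbind(s_idx, d_idx)] +
    stats::rnorm(nrow(resp), 0, cfg$item_noise_sd)
  # severity scale 0..4, centered at 2
  resp$rating <- pmin(4L, pmax(0L, as.integer(round(latent + 2))))
  resp$instrument <- factor_weights$instrument[match(resp$item_id, item_ids)]
  resp <- resp[order(resp$participant_id, resp$item_id), , drop = FALSE]
  row.names(resp) <- NULL
  list(responses = resp, factor_weights = factor_weights)
}

#' Write a synthetic bundle to CSV files
#'
#' Emits the same CSV schemas the loaders in this package read, plus a JSON
#' metadata file recording the seed and configuration.
#'
#' @param bundle an `info_bundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "info_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(bundle$trials_t1, "trials_t1.csv")
  wr(bundle$trials_t2, "trials_t2.csv")
  wr(bundle$participants, "participants.csv")
  wr(bundle$questionnaire, "questionnaire.csv")
  wr(bundle$factor_weights, "factor_weights.csv")
  wr(bundle$true_weights_t1, "true_weights_t1.csv")
  wr(bundle$true_weights_t2, "true_weights_t2.csv")
  meta <- file.path(dir, "metadata.json")
  cfg <- bundle$config
  cfg$population_cov_weights <- as.vector(cfg$population_cov_weights)
  cfg$rating_corr <- as.vector(cfg$rating_corr)
  jsonlite::write_json(unclass(cfg), meta, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta)
  invisible(files)
}
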