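---
title: "Motive decomposition of information seeking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motive decomposition of information seeking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery: the
models, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real data.

## The choice model

A participant rates, for each of ~40 stimuli, whether they want to receive
a piece of information on a six-point scale with no neutral point (−3..−1,
+1..+3). Separately they provide, on seven-point scales (−3..+3), proxies
for three utilities: usefulness (instrumental), expected feeling if the
information were known and if it were never known (whose difference is the
hedonic utility, −6..+6), and how often they think about the concept
(cognitive). The working model is linear:

\[
\text{choice}_{si} = \alpha_s + \beta_{1s} I_{si} + \beta_{2s} H_{si}
  + \beta_{3s} C_{si} + u_i + \varepsilon_{si}.
\]

Assumptions worth stating plainly: choice is treated as numeric and
interval-scaled (an ordinal model is out of scope), the utilities enter
additively with no interactions, and the item effect \(u_i\) is a random
intercept only.

Two estimators share this model. `fit_mixed_model()` estimates the
population fixed effects with by-participant random intercept and slopes
plus a by-item random intercept (`lme4`), each fixed term centered within
participant. `fit_subject_weights()` estimates \((\alpha_s,
\beta_{1s}, \beta_{2s}, \beta_{3s})\) per participant by OLS; slopes are
invariant to the centering, which the tests verify both ways.

### Estimation choices

- **ML, not REML, for comparison.** The candidate models differ in fixed
  effects, so restricted likelihoods are not comparable; all fits entering
  `compare_models()` use maximum likelihood. A `REML` flag exists for
  reporting final-model estimates.
- **Diagonal random-effects covariance by default.** With ~40 trials per
  participant, an unstructured 4×4 by-participant covariance frequently
  hits boundary or convergence trouble; independent random effects
  (`||` syntax) are markedly more robust and leave fixed effects nearly
  unchanged. Unstructured covariance is available
  (`random_cov = "unstructured"`).
- **No by-item random slopes.** Item random slopes are a known source of
  non-convergence in this design; the candidate space uses item intercepts
  only.
- **`n_obs` for BIC is the trial-level observation count.** BIC rankings
  depend on this convention, so it is stored on every fit and the
  identity `bic = k·log(n_obs) − 2·logLik` is re-asserted at fit time.
- **Satterthwaite degrees of freedom** (`lmerTest`) for fixed-effect
  t-tests, producing the fractional df this literature reports; the method
  is recorded in the fit object, and `ddf = "none"` skips it where only
  estimates are needed (it is the expensive part of a fit).
- **Candidate space.** `enumerate_model_space()` returns the full
  three-utility model plus its six strict subsets, and optionally the
  eight confidence-containing specs (confidence alone and joined with each
  utility subset) — 15 in total. Non-converged fits are reported but never
  ranked; exact BIC ties resolve to the smaller parameter count.

## Dominance classification

`classify_dominance()` compares the three weights by absolute magnitude by
default: a negative weight is a strong (avoidance-driving) motive, and
ratio thresholds on signed values are ill-defined under mixed signs. A
signed mode exists for sensitivity analysis. Thresholds are inclusive
(≥ 2 and ≥ 1.25), since the field's verbal rules ("at least 1.25 times")
are inclusive and the strictness of the 2× bound is not stated; an exact
tie for the largest magnitude is classified as no dominant motive. The
classification is invariant to positive rescaling of all three weights.

## Stability statistics

`beta_distance()` is the Euclidean distance between a participant's weight
triples at two sessions. The permutation test compares the matched mean
distance to the distribution of mean distances under random re-pairings of
session-2 data. Two decisions here were open:

- **Fixed points are excluded** from the permutations (every participant
  is truly mismatched, by rejection sampling over uniform permutations),
  matching the verbal description of the procedure; unrestricted
  permutations are a flag away (`allow_fixed_points`).
- **The actual pairing is not added to the null distribution**; the
  reported proportion is the share of mismatched draws whose mean distance
  exceeds the actual one.

For small cohorts `exhaustive_stability_test()` enumerates all admissible
permutations; the Monte-Carlo test is checked against it in the suite.
Note that under a true null (independent sessions) the reported proportion
is approximately uniform on [0, 1] — it is a p-value complement, not an
estimator of 0.5 — so calibration tests average it over replicate
cohorts.

ICCs are computed per motive after *profile-centering*: each
participant-session triple has its own mean across the three motives
subtracted, so the statistic measures agreement of the relative motive
profile. The source description of this centering admits more than one
reading; grand-mean centering and no centering are provided as options.
The ICC itself is the two-way random-effects, absolute-agreement,
single-measures form ICC(2,1), assembled from the two-way ANOVA mean
squares with an F-based p-value on (n−1, (n−1)(k−1)) df; the consistency
form ICC(3,1) is a flag. No installed package provides ICC directly, so
the mean-squares computation is implemented here and cross-checked in the
tests against an independent `aov`-based oracle. A non-positive
denominator (no between-subject variance) reports 0 with a warning rather
than a negative artifact.

## Psychopathology scoring and association

`score_dimensions()` z-scores each questionnaire item across participants
(sample SD; a toggle disables z-scoring for the raw-score sensitivity
check), multiplies by the item's published factor weight on each of the
three transdiagnostic dimensions, and sums within dimension. Zero-variance
items are z-scored to 0 (with a warning) rather than dropped, keeping the
weight-matrix mapping total. Participants missing any item are flagged
incomplete and excluded from association analyses.

The mixed ANOVA is realized as a repeated-measures ANCOVA via a
multivariate linear model with `car::Anova(..., idesign = ~dimension,
type = 3)` — the SPSS-style computation. Its between-subject stratum is
algebraically a regression on each participant's mean score, so every
covariate's main-effect F must equal the squared t of the same predictor
in `average_score_regression()`; the test suite asserts this equivalence
on every run rather than trusting it. Gender enters as a categorical
factor dummy-coded against the most frequent level (cohorts in this
literature report more than two levels); a single-level gender collapses
to the intercept with a warning. Partial correlations are
residual-on-residual Pearson correlations controlling age and gender, df
= n − 2 − (number of control columns). Per-questionnaire tests are
implemented as simple regressions of instrument totals on each weight
with Bonferroni correction across the nine instruments — the published
description ("one-way ANOVA" with a continuous predictor) is
under-specified, and this is the interpretation adopted.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the estimators
assume — it is a testbed, not a fit to any empirical dataset:

- per-subject weights \(w_s \sim \mathcal N(\mu, \Sigma)\), with default
  \(\mu = (0.114, 0.123, 0.091)\) (the regime typical of self-trait
  studies) and SDs (0.25, 0.15, 0.25) with mild (0.2) correlation, so
  that individual weights spread widely around modest population means;
- correlated latent utility ratings (default pairwise correlation 0.3,
  latent SD 1.5 so the seven-point scale is well used), with the hedonic
  latent split into two "feel" ratings whose difference carries it;
- thresholded discretization to the task scales: nearest level with
  clamping for seven-point scales; for the no-zero choice scale, latents
  in (−0.5, 0.5) map to ±1 by sign and an exact zero maps to +1 (the
  documented tie-break);
- latent choice \(\alpha_s + w_s\cdot u + \text{item} + \varepsilon\)
  with intercept mean 0.43 and SD 1.0, item-effect SD 0.3 and residual SD
  1.0 (choice-scale units), giving mean-choice distributions like those
  the task produces;
- session-2 weights mean-reverting with autocorrelation `stability_rho`
  (default 0.65): \(\mu + \rho(w−\mu) + \sqrt{1−\rho^2}\,\eta\), applied
  in latent weight space so that \(\rho\) maps interpretably onto ICC;
- a questionnaire whose subject-level latent composite equals
  `psych_coupling`·\(w_{3s}\) + age and gender terms + noise (defaults
  −1.05, −0.01/yr, +0.3 for female, residual SD 1.0), spread over 30
  items through a sparse positive factor-weight matrix and discretized to
  a 0–4 severity scale.

Because the latent choice is linear in the *emitted* utilities, switching
off noise, item effects and discretization makes per-subject OLS recover
the true weights to machine precision — the suite's exactness anchor.
With discretization on, the bounded choice scale clips extreme latents,
which biases recovered fixed effects slightly toward zero; at the default
settings this attenuation is about 0.01 and is covered by the recovery
tolerances.

What passing these tests does *not* show: the generator has no response
styles, no missingness, no item content, no heavy-tailed raters, and its
inter-rating correlation structure is a configurable placeholder (the
relevant empirical correlations are not built in). Results on synthetic
cohorts demonstrate the estimators' correctness and calibration, not
empirical claims about human information seeking.

## Problem sizes and tolerances in the test suite

The suite's scales are chosen to make the statistical checks sharp while
keeping a full run in the low minutes: exact-oracle checks at toy sizes;
parameter recovery over 20 cohorts of 300 participants × 40 trials
(2·SE coverage ≥ 90% across checks, mean absolute error < 0.03);
BIC selection over 50 cohorts of 40 × 40 generated from a strong,
well-separated full model (win rate ≥ 90%); permutation calibration as
the mean proportion over 12 null cohorts of 100 participants at 2,000
iterations; ICC recovery at 500 participants; and the planted
psychopathology coupling at 500 participants over 20 (power) and 40
(false-positive) replicates. Monte-Carlo tolerances were set from the
statistics' sampling variability before being frozen.

## Known limitations

- Linear treatment of a six-point ordinal response; no ordinal-logit
  variant.
- No Bayesian hierarchical estimation; per-subject OLS weights from ~40
  trials are noisy, which attenuates dominance percentages and ICCs
  relative to the latent truth.
- The exact df convention of other implementations of this analysis is
  not reproducible bit-for-bit (Satterthwaite is an approximation and the
  original convention is unstated).
- Factor weights for the psychopathology dimensions are an input; the
  package does not re-derive the factor analysis behind them.
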