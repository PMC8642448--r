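# infomotives

Why do people seek some information and actively avoid other information?
A useful working model treats each decision to know as a weighted
combination of three assessments the decision-maker brings to a piece of
information:

- **Instrumental utility** — how useful the information would be for
  guiding action (rated −3..+3);
- **Hedonic utility** — how one expects to feel knowing it minus how one
  expects to feel never knowing it (difference of two −3..+3 ratings,
  range −6..+6);
- **Cognitive utility** — how often one thinks about the concept the
  information concerns (rated −3..+3).

For participant *s* rating stimulus *i* on a six-point no-zero scale
(−3..−1, +1..+3, "definitely don't want to know" to "definitely want to
know"):

```
choice_si = α_s + β1_s · I_si + β2_s · H_si + β3_s · C_si + item_i + ε_si
```

The per-participant weights (β1, β2, β3) are the object of interest: they
define a three-dimensional "motive space" in which individuals differ, are
fairly stable over repeated sessions, and relate to self-reported mental
health. `infomotives` implements the full analysis pipeline for this
design, for researchers running Likert information-seeking tasks:

- validation and screening of long-format rating tables (attention-check
  and zero-variance exclusions);
- utility construction and within-participant centering;
- population-level estimation via linear mixed models (by-participant
  random intercept + slopes, by-item random intercept; `lme4`/`lmerTest`)
  with an AIC/BIC comparison over the 15-model candidate space (utility
  subsets and confidence-augmented variants);
- per-participant OLS weights and dominant-motive classification (a motive
  is *dominant* when its weight magnitude is ≥2× — or ≥1.25× — both
  others);
- longitudinal stability: the mismatched-pairing permutation test on mean
  Euclidean distance in weight space, and per-motive intraclass
  correlations ICC(2,1);
- transdiagnostic psychopathology scoring (weighted sums of z-scored
  questionnaire items on the Anxious-Depression, Social-Withdrawal and
  Compulsive-Behaviour/Intrusive-Thought dimensions) and its association
  with the motive weights (repeated-measures ANCOVA, average-score
  regression, partial correlations, per-questionnaire Bonferroni tests);
- a synthetic-data generator with the statistical structure the estimators
  assume, so the whole pipeline is testable without participant data.

## Worked example

The `analysis/` directory is a numbered workflow over the package API.
`01_simulate.R` draws a cohort of 80 participants × 40 stimuli × 2 sessions
(plus a nine-instrument questionnaire battery); the later scripts screen,
fit, profile and test it, writing tables under `results/`. A condensed
session:

```r
library(infomotives)

cfg <- generator_config(n_subjects = 80, n_trials = 40, timepoints = 2,
                        seed = 20)
report <- run_pipeline(cfg, n_perm = 10000, seed = 21)
```

Fixed effects of the full three-utility model (session 1):

```
 estimate     se    t    df        p         term
   0.5009 0.1089 4.60 101.4 1.22e-05  (Intercept)
   0.1463 0.0295 4.96  80.3 3.84e-06 instrumental
   0.1123 0.0231 4.86  80.2 5.80e-06      hedonic
   0.0801 0.0290 2.76  82.2 7.07e-03    cognitive
```

All three utilities carry significant positive weight: people want
information more when it is useful, when knowing feels better than not
knowing, and when it concerns things they think about often. The full
model beats all 14 alternatives on both criteria (ΔBIC ≈ 12.9 to the
runner-up), and individuals differ sharply — 45% of participants give one
motive more than twice the weight of the other two:

```
Dominance tiers (% of 80 participants):
 category  n percent
  twofold 36   45.00
   one_25 27   33.75
     none 17   21.25
```

Weights are stable across sessions three weeks apart: the mean distance
participants actually moved in weight space (0.390) is smaller than every
one of 10,000 mismatched re-pairings (mean difference 0.168), and each
motive's ICC is significant (0.37–0.44). Finally, the weight on cognitive
utility — and only that weight — tracks mental health (partial r = −0.297,
p = 0.009, controlling age and gender): participants who seek information
about what they think about most report fewer symptoms.

Run the whole workflow with:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

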