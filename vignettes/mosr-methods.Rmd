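---
title: "Multi-objective symbolic regression for 1-year postoperative mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective symbolic regression for 1-year postoperative mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

One-year mortality after major elective non-cardiac surgery runs at roughly
5–6%, and the patients who die are therefore heavily under-represented in any
patient-level table. Classifiers trained by maximising accuracy or likelihood
alone respond to this imbalance by predicting survival for everyone, which is
useless for the clinical purpose — flagging the minority of high-risk patients
who might benefit from prehabilitation or a different surgical plan.

`mosr` implements a genetic-programming (GP) symbolic-regression classifier
that optimises two objectives at once:

* **binary cross-entropy (BCE)** — the mean negative log-likelihood of the
  observed outcomes under the model's predicted probabilities, the usual
  proper-scoring objective; and
* **1 − F1** — the complement of the F1 score (harmonic mean of precision and
  recall) at the classification threshold, which directly penalises both
  missed deaths (false negatives) and over-calling (false positives).

A population of candidate models (expression trees) evolves under
non-dominated (Pareto) selection, so the final generation carries a front of
trade-offs between likelihood fit and F1 performance rather than a single
compromise. The protocol defaults are a population of 300 evolved for 500
generations; the worked examples and the test-suite use smaller populations
and fewer generations so that every analysis here runs on a single desktop
CPU core in minutes (the sizes actually used are stated with each analysis).

## Expression trees and protected arithmetic

A model is a rooted tree: internal nodes carry operators, leaves are feature
references or real constants. The operator set is

```
add, sub, mul, div, neg, log, exp, sqrt, min, max, ifg
```

with every operator *protected* so that finite inputs always give finite
outputs: `div(a, 0) = 1`, `log(x) = log(max(|x|, 1e-12))`, `exp` clamps its
input to ±50, `sqrt` acts on |x|, and `ifg(a, b, c, d)` returns `c` where
`a > b` and `d` otherwise. In addition every node's output is clamped to
±1e15, so no chain of multiplications can overflow to infinity. These rules
are arbitrary in their particular constants — some rule has to be picked —
and are chosen to keep both objectives finite for every tree the search can
construct.

The raw tree output is mapped to a probability by the logistic function, and
class predictions use a 0.5 threshold. Neither the link nor the threshold is
forced by the method; both are configuration options (`evolution_params`).

## The evolutionary loop

The multi-objective machinery is the canonical NSGA-II realisation:

1. **Initialisation**: ramped half-and-half at depths 2–6 (maximum depth 17,
   constants uniform on [−2, 2] since features are 0–1 scaled).
2. **Variation**: binary tournament on (dominance rank, crowding distance);
   subtree crossover with probability 0.8; subtree or point mutation with
   probability 0.2. Offspring exceeding the depth bound revert to their
   first parent.
3. **Survival**: elitist μ+λ truncation of parents ∪ offspring by
   (rank, crowding).

One deliberate addition: after truncation the per-objective best individuals
of the combined pool are explicitly retained. Standard crowding assigns
boundary individuals infinite distance, which keeps them in practice, but is
not a guarantee when more infinite-distance individuals exist than seats
remain; the explicit step makes the per-generation best-BCE and best-F1
traces exactly monotone, which the test-suite asserts as an invariant rather
than a tendency.

All randomness flows from a single master seed through named substreams
(initialisation, per-generation variation, splitting, subsampling,
attribution), so every stage is independently reproducible and the whole
pipeline is byte-deterministic under a fixed seed.

The final front is the rank-0 set of the last population, deduplicated by
serialized formula — "unique models" is read as enforcing formula
uniqueness. The single reported model is chosen from the front by ranking on
(AUC, sensitivity, specificity) descending lexicographically, with full ties
broken by smaller tree size and then by formula order.

## The synthetic cohort generator

The real cohort (a single-institution perioperative database) is not public,
so every stage is exercised on a synthetic cohort generator that emulates its
statistical structure:

* **Marginals** — 39 clinical features (demographics, comorbidities,
  medications, laboratory values, surgical specialty) and 46 cardiopulmonary
  exercise testing (CPET) summary variables. Continuous features are
  truncated normals parameterised to match published medians, interquartile
  ranges and ranges where those are available (age median 71 on [45, 89];
  BMI median 26.5 on [14, 39]; peak VE·VCO2 median 34.5; peak VO2 median
  17 ml·kg⁻¹·min⁻¹; anaerobic threshold median 10.5), and to clinically
  plausible values where they are not. Binary features are Bernoulli with
  the published cohort proportions (e.g. 69% male, 35% hypertension).
  A truncated normal cannot reproduce a skewed marginal exactly — the match
  is to location and range, not to the full shape.
* **Dependence** — independent marginals except for declared Gaussian-copula
  pairs; by default peak VO2 and the anaerobic threshold are rank-correlated
  0.7, a physiological-plausibility choice (the source data report no
  correlation structure).
* **Outcome mechanism** — logistic-additive on the log-odds scale:
  `logit P(death) = b0 + Σ coef · transform(x)`, with transforms `linear`
  (centred), `threshold_above` and `threshold_below`. The default effects
  plant the reported attribution directions: peak VE·VCO2 linear +0.15 per
  unit centred at 34.5 (odds ratio ≈ 2.3 per SD — poorer ventilatory
  efficiency raises risk), BMI > 28 kg·m⁻² coefficient −0.8 (the "obesity
  paradox" protective direction), peak VE·VO2 > 38 coefficient −0.6
  (protective), prior myocardial ischaemia +0.7 (harmful). The additive
  logistic form is the simplest mechanism that realises every reported
  direction while staying analytically checkable.
* **Prevalence calibration** — the intercept `b0 = −2.82635` was solved once
  by large-sample Monte Carlo (2 × 10⁶ draws) so that expected prevalence is
  5.5%; the test-suite verifies the realised prevalence over 20 seeds at
  n = 5000 stays within ±0.5 percentage points.
* **Missingness** — missing completely at random, cell-wise, outcome never
  missing. The real cohort's missingness mechanism is uncharacterised; MCAR
  is the neutral choice and exists to exercise complete-case filtering, not
  to model the real exclusion flow (which also removed patients for
  non-missingness reasons).

What passing tests on this generator do **not** show: performance on real
data. The generator has no unmeasured confounding, no informative
missingness, no measurement error, and only the declared dependence — it
validates the machinery and the recoverability of planted structure, nothing
more.

## Preprocessing

Complete-case filtering (patients with any missing value are excluded),
binary 0/1 encoding, one-hot encoding of sex, ethnicity and surgical
specialty with **no reference level dropped** (GP performs its own feature
selection and is indifferent to collinearity; the full indicator set keeps
every category nameable in a formula), and min–max scaling of continuous
features to [0, 1].

Two open choices were resolved as follows:

* Scaling parameters are fitted **on the training set only** and applied to
  test data (leakage-safe); values outside the fitted range scale outside
  [0, 1] and are deliberately not clipped. Whether the original analysis
  fitted on the whole dataset is unstated; `run_pipeline(scale_on = "all")`
  reproduces that alternative.
* A constant fitted column maps to 0 (the feature becomes inert).
* Ordinal clinical scores (ASA physical status) are treated as continuous.

The outcome-stratified 80/20 split allocates `floor(0.8 × class size)`
training seats per class and grants the remaining seats (up to
`round(0.8 n)`) to the largest class first. On a 1190-patient cohort with 66
events this reproduces exactly the published allocation: 952 training / 238
test patients with 52 / 14 events (66 × 0.8 = 52.8 floors to 52; the
negative class takes the remainder seat).

## Assessment protocol

* Metric panel: accuracy, sensitivity, specificity, F1, PPV, NPV, each from
  the confusion counts at the 0.5 threshold; 0/0 ratios are reported as an
  explicit undefined marker (`NA`), never silently as 0, except F1's
  standard convention (F1 = 0 when TP = 0 with FP+FN > 0).
* AUC in the Mann–Whitney form (probability a random positive outscores a
  random negative, ties at one half) — threshold-free.
* Grid-search 10-fold stratified cross-validation; inside each fold's
  training portion a stratified 90/10 division supplies the validation split
  the trainer uses for its own model selection, and the setting with the
  best mean held-out-fold F1 wins. The "90/10 division" wording is
  ambiguous between this reading and a separate holdout; the inner-split
  reading was chosen because it gives every fold its own selection data.
  The tuned dimensions default to population size, mutation probability and
  maximum depth (the original tuned set is unstated).
* Repeated test evaluation: 10 runs, each on a stratified 90% subset of the
  test set drawn without replacement, metrics averaged with SD; stratified
  subsampling keeps at least one event per run at 5.5% prevalence.
* Calibration bins: ten equal-width probability bins with per-bin mean
  predicted probability, observed event rate and count.
* Consistency: per-metric train − test differences (`overfit_gap`).

## Shapley attribution

Model-agnostic Shapley values with the marginal (interventional) value
function: v(S) is the mean model output over a background set with the
features in S pinned to the explained patient's values. Attribution is on
the probability scale by default (how beeswarm plots for classifiers are
read); the raw-score scale is a flag. Exact enumeration is used up to 12
features; beyond that, a permutation-sampling estimator with per-feature
Monte-Carlo standard errors. Because each permutation's marginal
contributions telescope from v(∅) to v(all), the estimator is exactly
additive by construction — no residual redistribution step is needed — and
only the split between features carries sampling error. Features a formula
never references are null players with exactly zero attribution, so
computation is restricted to referenced features without approximation.

`summarize_importance` ranks features by mean |attribution| across patients
and summarises direction as the correlation between each feature's
attribution and its value.

## Numerical choices and degenerate inputs

* BCE probabilities are clipped to [1e-12, 1 − 1e-12].
* Crowding distance: boundary individuals get +∞; a zero objective range
  contributes 0 (no division by zero); ties are ordered stably.
* Dominance is ≤ on both objectives with < somewhere; duplicated objective
  vectors share a front.
* Empty cohorts after filtering, single-class label vectors, folds losing a
  class, unknown categories, unresolved feature references and malformed
  formulas are all explicit errors, not silent coercions.
* `sample_cohort(n = 0)` returns an empty table with the full column schema.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the test-suite run the method at
desktop scale, chosen once: cohort n = 1190 (the study size), population
150, 60 generations, maximum depth 10 for the end-to-end analyses;
population 100 / 50 generations for planted-recovery checks; population 300
/ 500 generations remain the package defaults for a full run. Attribution
explains a seeded subsample of test patients (60–100) against a 50–100-row
background. At these sizes a full pipeline run takes a few minutes.

## Known limitations

* At the study prevalence (5.5%, 66 events in 1190 patients) and desktop
  search budgets, the evolved models reliably recover the dominant planted
  effect (peak VE·VCO2) but often ignore the weaker planted effects (the
  BMI > 28 and VE·VO2 > 38 protective thresholds): with ~50 training events
  their marginal value to either objective is small relative to search
  noise. Recovering secondary effects appears to need either the full
  300 × 500 search budget, more events, or both. The test-suite asserts the
  secondary-direction recovery as specified and reports its outcome honestly
  rather than weakening the check.
* The F1 objective is threshold-coupled (fixed 0.5); models on the BCE end
  of the front can have excellent likelihood and AUC yet predict no
  positives at 0.5, and the (AUC, sensitivity, specificity) selection key
  can prefer them. Selecting on a validation split (as `gp_trainer` does
  inside cross-validation) mitigates this.
* Truncated-normal marginals cannot reproduce skewed laboratory
  distributions; the generator matches location and range only.
* The permutation estimator's standard errors assume independent
  permutations; they say nothing about background-set sampling error.
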