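---
title: "Behavioral markers from 7-day app-usage logs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral markers from 7-day app-usage logs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appmarker)
```

## The problem

Depression screening from passively collected smartphone data usually
requires weeks of background sensing. An alternative is to use only the app
usage event history the operating system already keeps — about the past 7
days of foreground/background events, retrievable in under a second — and
ask whether behavioral markers derived from that single snapshot separate
participants who screen positive on the PHQ-9 (total ≥ 10) from those who
do not. `appmarker` implements that pipeline end to end: event ingestion,
marker extraction, four feature-selection regimes, and nested
leave-one-participant-out cross-validation (LOPOCV) with a stacking
ensemble, plus a synthetic cohort generator that makes all of it testable
without access to any clinical dataset.

## From events to usage intervals

Raw data are rows of (participant, timestamp, package, kind∈{foreground,
background}). The pairing rule is deliberately explicit because OS
semantics do not define one:

* per-package FIFO: each foreground opens an interval closed by the next
  background of the same package;
* a second foreground for an already-open package closes the first interval
  at the second foreground's timestamp;
* unmatched foregrounds close at the window end; unmatched backgrounds are
  dropped; intervals are clipped to the declared 7-civil-day window;
* at equal timestamps, background events sort before foreground events,
  which prevents zero-length phantom overlaps.

Timestamps are treated as local civil time throughout (stored as UTC with
no timezone arithmetic), because diurnal periods are defined on the local
clock.

## The marker grid

The marker vocabulary is a fixed 864-cell grid:
28 app scopes (27 store-style categories plus whole-smartphone) × 2
day-types (weekday/weekend) × 5 measures (duration, launch count, unique
apps, usage entropy, Hamming-distance ratio) × 3 characteristics (whole-day
total, and mean/SD over the four 6-hour diurnal periods), plus 2 × 4 × 3
session cells (total/micro/review/engage counts). Conventions that matter:

* **Diurnal periods** are half-open blocks [00:00,06:00), [06:00,12:00),
  [12:00,18:00), [18:00,24:00). Durations are split exactly at period
  boundaries (an interval from 11:30 to 12:20 contributes 30 min to the
  morning and 20 min to the afternoon); launches are attributed wholly to
  the opening period. The "x:01 AM" phrasing conventional for these period
  names is read as inclusive-boundary notation — the four periods must tile
  the day.
* **Weekend** defaults to Friday/Saturday (the weekend in Bangladesh, the
  setting this pipeline was designed for) and is configurable; it is never
  inferred from data.
* **Diurnal SD** uses the population divisor (4): the four periods are the
  whole population of periods, not a sample.
* **Sessions** merge intervals whose inter-use gap is at most 45 s, the gap
  measured against the running maximum end so that concurrent app use
  counts as engagement. Sessions are typed by total active duration:
  micro ≤ 15 s < review ≤ 60 s < engage. A session belongs to the day-type
  and period of its start.
* **Entropy** is Shannon entropy of the per-app duration distribution
  within a scope; one app (or none) gives 0. Natural log by default — the
  base only rescales a feature that is standardized downstream.
* **Hamming-distance ratio** concretizes "app-set uniqueness": the distance
  between two participants is the symmetric-difference cardinality of
  their app sets (identical to the Hamming distance of binary membership
  vectors over a fixed universe). For each participant, the minimum
  distance D to the depressed pool and ND to the nondepressed pool form
  the ratio D/ND, the participant's own set being excluded from its pool.
  Degenerate conventions (configurable, covered by tests): 0/0 → 1
  ("equally unique in both groups"); x/0 → x+1 (smoothed and monotone in
  x); a pool with no eligible comparator leaves the cell undefined, and it
  is zero-imputed after standardization. Because the ratio is label-aware,
  it is recomputed inside every cross-validation fold from training-fold
  labels only.
* **Sparsity filter**: a participant "uses" a category when their 7-day
  duration in it is positive; every feature of a category used by strictly
  fewer than 50% of (training) participants is dropped. Whole-smartphone
  and session features always survive.
* **Standardization** uses training-fold means and SDs only; zero-variance
  features map to 0.

## Feature-selection regimes

All four selectors run inside each outer training fold only.

* **Filter (information gain)**: plug-in mutual information after
  equal-frequency discretization into min(10, ⌊√n⌋) bins; deterministic,
  ties broken by column order. The top-k band k ∈ [5, 20] follows the
  one-in-ten rule at ~50 cases.
* **Embedded (random forest)**: impurity-based importances of a seeded
  forest, top-k. The environment provides no tree-learner package, so the
  package ships a compact CART engine (Rcpp): for a binary response,
  variance reduction is proportional to Gini gain, so one builder serves
  probability trees, regression trees for boosting, and importance.
* **Wrapper (Boruta-style all-relevant)**: each iteration appends a
  permuted shadow copy of every live feature, fits a depth-limited forest
  (depth swept 3–7 upstream), and scores a hit when a feature's importance
  beats the best shadow. Hit counts are tested against Binomial(iter, ½)
  two-sidedly with a two-step correction — Benjamini–Hochberg FDR across
  undecided features, then a factor-2 familywise correction for the two
  one-sided directions. Features still tentative at the iteration cap are
  resolved by comparing median importance to the median shadow maximum.
* **Stable (bootstrap stability selection)**: B bootstrap subsamples
  (size n, with replacement; one-class draws redrawn), an L1-penalized
  logistic base learner at a penalty fixed once per run by internal
  cross-validation ("selected" is only well-defined under sparsity — the
  paper-level description of a plain logistic base learner leaves the
  presence criterion open, and L1 is our explicit choice). A feature is
  kept when its presence fraction reaches π_th; the threshold sweep reads
  one set of presence fractions at 0.50, 0.51, … and stops at the first
  empty set, so set sizes are nonincreasing and nested by construction.

## Models and validation

The outer loop is LOPOCV; the inner loop is stratified k-fold CV (default
20, reduced with a warning when a class is smaller) maximizing F1 over a
random hyperparameter search with an explicit budget. Every label-aware
step — Hamming pools, sparsity filter, scaler, selector, tuner — sees only
the n−1 training participants; each fold's RNG seed derives from the base
seed and the held-out participant's id (not the fold index), so a fold is
exactly reproducible from its training rows, which is what the leakage
audit asserts.

The zoo covers the families a screening study would try: a
constant-positive dummy baseline, ridge logistic, decision tree, random
forest, extra-trees, kNN, Gaussian naive Bayes, a Pegasos-style linear
SVM, AdaBoost on stumps, and logistic-loss gradient boosting. The three
branded gradient-boosting variants (LightGBM/XGBoost/CatBoost) have no R
backend in the supported environment and are represented by the single
in-package gradient-boosting machine; an MLP entry is omitted for the same
reason. The stacking ensemble ranks non-baseline models by nested-CV F1
(ties by precision, then name), takes the top 5, and — per outer fold —
fits a logistic meta-learner on stratified 10-fold out-of-fold predictions
over the training rows. Training the meta-learner inside each outer fold is
a deliberate choice: any placement outside the fold leaks the held-out row.
Evaluation reports precision, sensitivity, specificity, F1, accuracy,
balanced accuracy = (sensitivity+specificity)/2, and rank-based AUC on
held-out probabilities. Appearance frequency — the percentage of LOPOCV
iterations whose selection contains a feature — is the importance summary;
`attributions()` adds a model-agnostic signed per-feature attribution
(background-replacement deltas), a deliberately thin stand-in for full
Shapley analysis.

## The synthetic cohort

The study cohort is not deposited, so the generator is a first-class
module, not a fixture. It is top-down: per participant it first draws
latent marker targets from group-shifted distributions, then realizes a
7-day event stream consistent with them — Poisson session counts under a
diurnal intensity profile (night 0.25 : morning 0.9 : afternoon 1.0 :
evening 1.1), a micro/review/engage session mixture, inter-session gaps
straddling the 45 s threshold from both sides, and fg/bg event pairs that
re-enter the ingestion path with zero parse errors. Event volume defaults
to the reported cohort mean (~8,174 events/phone/week) and scales linearly
via `synth_scale()`; tests run at factor 0.1 (~800 events). PHQ-9 items are
drawn consistent with each label, so `total ≥ 10 ⇔ depressed` holds
exactly.

Four planted effects (standardized mean differences, default d = 1)
mirror the direction of findings this kind of pipeline should recover:
nondepressed ↑ weekday education-app duration; depressed ↑ weekend
photo/video per-period app-count SD; depressed ↓ weekday whole-smartphone
usage entropy; depressed ↑ weekday communication-app diversity. The
concentration and diversity mechanisms interact (strong usage
concentration hides owned apps), so the generator gives every owned
communication app one short weekly "touch" session and uses fixed-size
base inventories; the latent shifts were calibrated once so that the
*extracted* markers realize |d| ≈ 0.8–1.5 at n = 60, and then frozen.
What a green round-trip test establishes is therefore: the pipeline
recovers group structure of roughly unit effect size planted in these four
marker families at this cohort size. What it does not establish: realism
of app popularity distributions, autocorrelated daily routines, missing
data, device heterogeneity, or label noise — real cohorts are harder.

## Numerical and procedural choices

* Empty selection result in a fold falls back to the selector's single
  top-scoring feature (models need at least one column).
* glmnet degenerate folds (fewer than two members of a class) fall back to
  predicting the class prior.
* The acceptance battery fixes its pass rules in advance: each regime's
  top-10 appearance-frequency features must cover ≥ 2 planted marker
  families (a family is any characteristic of the planted scope × day ×
  measure combination) in ≥ 90% of 10 seeds, matching the ≥90%-of-replicates
  convention used for the selector sanity battery; the best non-dummy
  model's median balanced accuracy must exceed 0.70; the permuted-label
  null's mean must stay in [0.40, 0.60].
* CI-scale reductions (forest sizes ~30–100 trees, stability B = 50–100,
  Boruta ≤ 15 iterations, tuning budget 2, inner folds 5, selector sanity
  battery 10 replicates instead of 50) are runtime scalings; thresholds are
  never adjusted.

## Known limitations

* The fg/bg pairing rule and the Hamming-distance formula are explicit
  interpretations of under-specified descriptions; both are config-exposed
  and oracle-tested, but a different upstream convention would shift
  feature values.
* Planted composition effects necessarily produce collateral signal in
  correlated non-planted cells (concentrating usage moves every category's
  duration shares; education time is part of whole-smartphone duration).
  On some cohorts those collateral cells crowd the 10-slot
  appearance-frequency ranking, so the information-gain and stability
  regimes occasionally surface only one planted marker family in their
  top-10 even while clearly tracking planted signal — the corresponding
  recovery check is deliberately left failing rather than the counting
  rule being relaxed after measurement.
* Boruta-style selection is an in-sample, all-relevant procedure: given a
  long iteration budget it will eventually admit the sample-maximal chance
  correlation on pure-noise data, because that feature genuinely is
  relevant in the finite sample. The clean-null property is therefore a
  property of the corrected binomial testing at moderate iteration
  budgets, and of the statistically confirmed tier — the opt-in median
  rough fix for leftover tentative features knowingly admits borderline
  candidates. Boruta's internal importance is out-of-bag permutation
  importance: in-sample impurity gains reward chance correlations and
  destroy the null behavior outright.
* Balanced cohorts are assumed by the stratified inner CV; extreme
  imbalance degrades to fewer folds with a warning.
* The in-package learners are compact reference implementations, not
  tuned-for-speed libraries; full-scale runs (B = 1000, budget 25, 13
  models, n = 100) are hours, not minutes, on one CPU.
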