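---
title: "Methods: gated inheritance voting and its companion procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated inheritance voting and its companion procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the model and its assumptions, the parameters that matter, the numerical
conventions, the design decisions taken where the design was genuinely
open, and what the synthetic cohorts do and do not establish.

## The classification model

The ensemble couples three probabilistic base classifiers — a primary
C0 and two secondaries C1, C2 — through a *confidence gate*. Writing
`p0[i, ]` for C0's class-probability row on sample *i* and θ ∈ [0, 1]
for the gate width:

* **inheritance**: if `max(p0[i, ]) >= 1 - θ`, the sample takes C0's
  argmax prediction directly;
* **weighted voting**: otherwise the class scores are
  `s[i, c] = w_c0 p0[i, c] + w_c1 p1[i, c] + w_c2 p2[i, c]` and the
  prediction is `argmax_c s[i, c]` (soft voting, the default); hard
  voting replaces each probability row by a one-hot argmax vote before
  weighting.

The intuition: a strong primary classifier should not be second-guessed
where it is nearly certain; the secondaries only matter in the uncertain
region, where their disagreement carries information. θ = 1 recovers the
pure primary classifier (every sample inherits); θ = 0 sends everything
except probability-1 predictions to the vote.

Assumptions worth stating. (1) All three learners must emit calibratable
class probabilities on a shared class order; the package fixes that
order by the label encoding (alphabetical `AGA = 0, LGA = 1, SGA = 2`
by default, configurable). (2) The gate trusts C0's probabilities
literally: an overconfident primary learner inherits mistakes. This is a
property of the method, not a defect of the implementation, and is the
reason θ is tuned rather than fixed.

### Numerical conventions

* The gate comparison is **closed** (`>=`), so `θ = 0` still inherits
  samples predicted with probability exactly 1.
* Voting weights are **not renormalized**: the argmax is invariant to a
  positive rescaling, and keeping the user's numbers makes the tuned
  operating point `(0.19, 0.01, 0.73)` (which sums to 0.93) reportable
  verbatim. Where normalization matters scientifically — the importance
  aggregation — it is applied explicitly.
* Exact score ties break towards the **lowest class index** under the
  active encoding. This is deterministic, documented, and exercised by
  the tests; with continuous probabilities ties essentially occur only
  in degenerate configurations.
* Misaligned probability blocks (different sample counts) are an error,
  never silently recycled.

### Base learners

Five kinds satisfy the probability contract: random forest
(`randomForest`), gradient-boosted trees (`xgboost`, `multi:softprob`),
support-vector machines (`e1071`, Platt-scaled probabilities),
k-nearest-neighbours (`caret::knn3`), and a CART-style decision tree
(`rpart`). Hyperparameters pass through to the backend. The shipped
defaults carry the tuned values of the motivating study where the R
backend has a direct equivalent — KNN `k = 24`, SVM `cost = 100` with a
degree-2 polynomial kernel, gradient boosting with `eta = 0.01`,
`max_depth = 4`, `min_child_weight = 2`, `colsample_bytree = 0.5`,
`colsample_bylevel = 0.6`, 1000 rounds — and backend defaults elsewhere:
sklearn-style impurity-criterion names and random-forest depth caps have
no `randomForest` counterpart, so they are not emulated. Every fit is
seeded; two fits with the same spec reproduce each other exactly.

## Preprocessing

The cleaning stage follows the usual order for this kind of cohort:

1. **Duplicate removal.** A duplicate is an *exact* match across all
   raw columns, with missing matching missing; later occurrences are
   dropped. Exact equality is the only reproducible reading of
   "duplication" for mixed continuous/binary records, and the operation
   is idempotent.
2. **Invalid-row removal.** A row is invalid if any cell was
   unparseable at read time or any continuous value falls outside its
   schema validity range. Unparseable cells are tracked separately from
   missing cells precisely so the report can count both. The validity
   ranges ship in the schema as broad clinical-plausibility bounds —
   the package deliberately makes them configuration, not code.
3. **Median imputation** of continuous columns. Medians are fitted on a
   declared row set (the training rows, in a split pipeline) and applied
   everywhere, so no test-set statistic leaks into training. Observed
   cells are never altered.
4. **Standardization** with the *population* (divisor n) standard
   deviation. The convention is arbitrary but must be fixed; population
   sd matches the default of the toolchain family this design came
   from. Constant columns are centred and their scale clamped to 1,
   avoiding a division by zero while keeping the column.
5. **SMOTE with optional undersampling.** Synthetic minority samples
   are built canonically: pick a class member, pick one of its
   `neighbors = 5` nearest same-class neighbours (Euclidean), and draw
   uniformly on the connecting segment — so every synthetic row is a
   convex combination of two same-class originals, a property the tests
   verify by solving for the interpolation coefficient. `"smote"`
   raises every class to the majority count; `"smote+undersample"`
   moves all classes to target proportions of the original total,
   undersampling majorities at random without replacement.

**Leakage policy.** Resampling belongs *after* the train/test split and
only on training rows. A balanced test set (as a pre-split resample
produces) inflates minority-class metrics with synthetic neighbours of
test points. The package's functions are therefore all fit/apply pairs
scoped to row sets, and the resampler is documented as
training-rows-only; a user wanting the resample-then-split order for
comparability with published numbers can still compose it, but it is
not the default.

## Tuning (gate, weights, secondaries)

`tune_wivela()` jointly searches every unordered secondary pair from a
candidate pool, every θ candidate, and every weight triple, scoring each
configuration by repeated stratified CV accuracy. Implementation note
with scientific consequences: base learners are fitted **once per
fold** and their held-out probability blocks cached, so the
(pair, θ, W) sweep costs only argmax arithmetic. This makes a joint
search tractable where a naive refit-per-configuration search would
force a coarser grid. The default grid (θ ∈ {0.0005, …, 0.1}, weights
∈ {0.01, …, 1.0}) contains the motivating study's optimum. Ties break
by smaller accuracy standard deviation, then lexicographically smaller
weights — arbitrary but total, so tuning is reproducible. Tuning CV
defaults to 10-fold × 3 repeats; the heavier protocol is reserved for
final evaluation.

## Feature importance and the threshold sweep

Per-learner conventions: random forest contributes mean decrease in
impurity (the weighted impurity reduction attributed to a feature's
splits, averaged over trees — implemented via
`randomForest::importance(type = 2)`, which matches the verbal
definition "total reduction in the criterion brought by that feature");
gradient boosting contributes gain (features never used score 0); the
SVM contributes the mean of |w| over the N(N−1) ordered one-vs-one
classifiers. Since coefficients exist only for linear kernels, a
non-linear predictive SVM gets **linear-kernel surrogates** refitted
pairwise on the same training data solely for importance extraction,
and the importance vector's normalization note records this. The mean
(rather than sum or max) over pairs is a choice; any of the three gives
the same ranking up to scale for the mean-vs-sum pair, and the mean
keeps scores comparable across class counts.

The aggregation
`fi_i = (|xgb_i| w_XGB + |svm_i| w_SVM + |rf_i| w_RF) / (w_XGB + w_SVM + w_RF)`
is a convex combination, hence bounded per-feature by the min and max
of its inputs and invariant to rescaling all weights — both properties
are tested, the denominator's weight set being read as exactly the
three weights in the numerator. Note the aggregation mixes scores on
different natural scales (impurity units, gain fractions, |w|); the
combined score is a relevance *ranking* device, not a calibrated
effect size, and the package makes no causal claim for it.

`feature_sweep()` turns a score vector into a nested family of feature
subsets (each distinct |score|, descending, is an inclusion threshold)
and scores each subset by repeated stratified CV. The selection rule
"highest mean accuracy, or close to it, with smaller deviation and
fewer features" is made deterministic as the lexicographic order
(mean accuracy ↓, sd ↑, feature count ↑), with an optional tolerance τ
(default 0) that treats accuracies within τ of the maximum as equal
first — τ is the package's explicit rendering of "close to it".
The recorded accuracy deltas are diagnostic (they show the
rise-then-plateau shape that indicates a trustworthy importance list)
and are not used by the selection rule. Duplicate scores collapse to
one threshold; an all-zero vector yields a single row with all
features.

## Evaluation protocol

A stratified 75/25 split; repeated stratified k-fold CV (10-fold, 100
repeats in the full protocol) on the training portion; accuracy and
negative mean squared error on integer-encoded labels, with the
encoding recorded in the report — a three-class MSE is only meaningful
relative to a stated encoding, and alphabetical `AGA=0, LGA=1, SGA=2`
is the toolchain-default reading. Per-repeat fold assignments are drawn
with seed `base_seed + repeat`, so any model evaluated with the same
seed sees identical folds; `cv_compare()` exploits this plus the fact
that the ensemble already computes each base learner's held-out
probability block, scoring ensemble and bases on identical folds at no
extra fitting cost. The classification report uses the standard
per-class precision/recall/F1 with supports, macro and weighted
averages; zero denominators yield 0 with an explicit flag and warning.

## The synthetic cohort generator

The generator is first-class, tested code, because the motivating
cohort is private: it produces data with the statistical structure the
pipeline assumes, so every stage is testable without any download.

What it emulates, with the study-shaped defaults
(`sga_lga_synthetic_spec()`): 7943 rows over a 34-column first-trimester
layout; exact class prevalences 5.33 / 11.68 / 82.99% (largest-remainder
realization by default, multinomial draws optionally); raw `sga`/`lga`
indicator columns merged downstream into the three-level outcome;
class-conditional Gaussian shifts on the maternal, obstetric, and
biomarker attributes the motivating study flags as relevant, and
class-conditional Bernoulli rates on the obstetric history flags;
missingness concentrated as a joint lipid-panel dropout (~13.4% of rows
lose TC, TG, HDL, LDL together, emulating a skipped laboratory panel)
plus trace per-column rates in the glucose columns; and 45 planted
rows — 20 exact duplicates and 25 range violations — whose indices the
ground-truth record exposes so cleaning can be verified row by row.
Values generated for ranged columns are clipped to their validity
ranges, so *only* deliberately planted rows are invalid.

Effect sizes are a study condition, set once: the class-conditional
shifts (mostly 0.3–1 sd per feature, plus strong obstetric flags such
as fetal growth restriction at 45% in SGA vs 2% in AGA) were calibrated
so a tuned random forest sits near 0.90 cross-validated accuracy at a
few thousand rows — the operating regime in which comparing ensemble
variants is informative. They live in the spec object, not in code
paths.

What it does **not** emulate, hence what passing tests do not show:
real joint covariance between biomarkers (features are conditionally
independent given the class), informative missingness (dropout is
completely at random given the panel event), measurement error
structure, site or calendar effects, or clinical plausibility beyond
marginal ranges. Results on synthetic cohorts validate the *machinery*
— bookkeeping, gating algebra, selection behaviour, protocol
correctness — not clinical performance claims.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full study-shaped
generation (n = 7943) for bookkeeping, a 3000-row cohort with 10
repeats of 10-fold CV for the ensemble-vs-base benchmark (the ensemble
is first tuned on a coarse grid containing degenerate single-learner
weight triples, mirroring the tune-then-compare protocol), 20-seed
recovery runs at n = 450 for the feature sweep, and 1000 random trials
for the aggregation bounds. These sizes were chosen as the smallest at
which the respective statistical statements are stable across seeds;
every run is reproducible from the seed, and the sweep and tuning
grids used are stated in the calling code.

## Known limitations

* SVM probability output relies on Platt scaling, which is itself
  cross-validated internally by the backend; probabilities are
  reproducible under a fixed seed but not calibrated guarantees.
* The SMOTE implementation interpolates *all* feature columns,
  including binary ones, as canonical SMOTE does; synthetic rows can
  therefore carry fractional values in binary columns. Tree and kernel
  learners handle this; analysts reading resampled tables should be
  aware of it.
* `feature_sweep()` refits the supplied classifier once per threshold
  per fold; with the ensemble as the classifier this is the most
  expensive operation in the package, and the repeat count is the
  knob to trade precision for time.
* Categorical columns are carried through I/O and cleaning but must be
  recoded numerically before modelling; the shipped schema uses binary
  encodings throughout.
* The importance aggregation inherits each backend's biases (impurity
  importance favours high-cardinality features; gain depends on
  boosting hyperparameters). The threshold sweep is the corrective
  lens: an untrustworthy importance list shows up as a non-plateauing
  accuracy curve.
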