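# wivela

Weighted inheritance voting ensemble learning for imbalanced multi-class
clinical cohorts, with the companion procedures a full analysis needs:
leakage-aware preprocessing, a feature-importance threshold-sweep feature
selector, cross-validated tuning of the ensemble's operating point,
weighted aggregation of heterogeneous feature-importance scores, a
repeated stratified cross-validation protocol, and a synthetic cohort
generator.

## The problem and who this is for

Classifying fetuses as small, appropriate, or large for gestational age
(SGA / AGA / LGA) from first-trimester maternal data is a heavily
imbalanced three-class problem (roughly 83% / 12% / 5% prevalence), and
the clinical question is twofold: predict the class early, and rank the
maternal, obstetric, and biomarker attributes that drive the prediction.
`wivela` is aimed at biostatisticians and ML practitioners working on
this kind of tabular, imbalanced, risk-factor-oriented classification —
obstetric cohorts being the motivating case, but nothing in the package
is specific to them.

## The classifier

Three probabilistic base learners are fitted on identical training rows:
a primary classifier C0 and two secondaries C1, C2. For a sample *i*
with primary class-probability row `p0[i, ]`:

* if `max(p0[i, ]) >= 1 - θ`, the sample **inherits** the primary
  classifier's prediction (it is "confident");
* otherwise the sample is decided by **weighted voting** with weights
  `W = (w_C0, w_C1, w_C2)`: soft voting scores each class *c* by
  `Σ_k w_k · p_k[i, c]` and takes the argmax (hard voting weights
  one-hot votes instead).

The gate width θ and the weights W are tuned by cross-validated grid
search (`tune_wivela()`); the operating point reported for the motivating
obstetric cohort is `(θ, w_RF, w_XGB, w_SVM) = (0.001, 0.19, 0.01, 0.73)`
with a random forest primary.

Feature relevance is aggregated across the three learners as

```
fi_i = (|xgb_i|·w_XGB + |svm_i|·w_SVM + |rf_i|·w_RF) / (w_XGB + w_SVM + w_RF)
```

a convex combination of the absolute per-learner scores (random-forest
mean decrease in impurity, gradient-boosting gain, mean |w| over
one-vs-one linear SVM classifiers). The feature selector
(`feature_sweep()`) treats each distinct absolute importance score as an
inclusion threshold, scores the nested feature subsets by repeated
stratified CV, and `select_best()` picks the group with the highest mean
accuracy, smallest standard deviation, and fewest features, in that
order.

## Worked example

```r
library(wivela)

# a study-shaped synthetic cohort: 7943 rows, 34 columns, planted
# duplicate/invalid rows, lipid-panel missingness
gen    <- generate_cohort(sga_lga_synthetic_spec(seed = 7))
cohort <- build_outcome(gen$cohort)          # merge sga/lga indicators
clean  <- remove_duplicates_and_invalid(cohort)
print(clean$report)
#> Preprocessing report
#>   rows: 7943 raw = 20 duplicates + 25 invalid + 7898 retained
#>   missing values by column:
#>     fpg                          26
#>     tc                           1019
#>     tg                           1030
#>     hdl                          1023
#>     ldl                          1032
#>     ogtt_0h                      54
#>     ogtt_1h                      46
#>     ogtt_2h                      46
#>   1188 rows with missing values, 4276 missing cells total
#>   classes: AGA=6556 (83.01%), LGA=920 (11.65%), SGA=422 (5.34%)
```

45 planted rows are removed (leaving 7898), missingness concentrates in
the four lipid columns, and the class mix stays at the study prevalences.
Continuing to the classifier:

```r
co <- clean$cohort
co <- apply_impute(fit_impute(co), co)       # median imputation
co <- apply_scaler(fit_scaler(co), co)       # standardization

sp  <- stratified_split(co, test_fraction = 0.25, seed = 7)
fit <- fit_wivela(sp$train, ensemble_config())   # RF + XGB + SVM, θ = 0.001
pred <- predict(fit, sp$test)
classification_report(cohort_outcome(sp$test), pred$labels)
```

`predict()` also returns the gate mask and the three probability blocks,
so every prediction can be audited sample by sample. The command-line
interface wraps the same functions:

```sh
Rscript inst/cli/wivela.R simulate   --config cfg.yml --n-rows 7943
Rscript inst/cli/wivela.R preprocess --config cfg.yml --data cohort.csv
Rscript inst/cli/wivela.R train      --config cfg.yml --train preprocessed.csv
```

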