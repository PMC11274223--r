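# Shared fixtures: tiny schemas and cohorts built in code.

tiny_schema <- function() {
  cohort_schema(
    column_meta("age", "continuous", lower = 0, upper = 100),
    column_meta("hdl", "continuous"),
    column_meta("flag", "binary")
  )
}

tiny_cohort <- function(age = c(30, 25, 40), hdl = c(1.9, NA, 2.2),
                        flag = c(0, 1, 0), outcome = NULL) {
  cohort_table(tibble::tibble(age = age, hdl = hdl, flag = flag),
               tiny_schema(), outcome = outcome)
}

# a small labelled cohort with signal, for model-level tests
signal_cohort <- function(n = 240, shift = 1.5, seed = 42) {
  generate_cohort(toy_cohort_spec(n_rows = n, n_informative = 3,
                                  n_noise = 2, shift = shift,
                                  seed = seed))$cohort
}

fast_tree_spec <- function(seed = 1L) {
  base_learner_spec("decision-tree", seed = seed)
}

fast_rf_spec <- function(ntree = 100, seed = 1L) {
  base_learner_spec("random-forest", list(ntree = ntree), seed = seed)
}

fast_ensemble_config <- function(theta = 0.1, weights = c(1, 1, 1),
                                 seed = 1L) {
  ensemble_config(
    theta = theta, weights = weights,
    learners = list(
      c0 = fast_rf_spec(60, seed),
      c1 = base_learner_spec("decision-tree", seed = seed),
      c2 = base_learner_spec("k-nearest-neighbors", list(k = 7),
                             seed = seed)))
}

# factory helpers for repeated_cv
rf_factory <- function(ntree = 100, seed = 1L) {
  function(train) fit_base_learner(fast_rf_spec(ntree, seed),
                                   feature_matrix(train),
                                   cohort_outcome(train))
}

# Brute-force per-sample recomposition of the gated-voting prediction from
# the exposed probability blocks, gate mask and weights (soft voting).
# Independent of the package's vectorized path: plain loops and which.max.
recompose_predictions <- function(pred, config, levels) {
  n <- nrow(pred$blocks$c0)
  out <- character(n)
  for (i in seq_len(n)) {
    p0 <- pred$blocks$c0[i, ]
    if (max(p0) >= 1 - config$theta) {
      out[i] <- levels[which.max(p0)]
    } else {
      s <- config$weights[["c0"]] * p0 +
        config$weights[["c1"]] * pred$blocks$c1[i, ] +
        config$weights[["c2"]] * pred$blocks$c2[i, ]
      out[i] <- levels[which.max(s)]
    }
  }
  out
}

constant_factory <- function(label) {
  function(train) {
    force(label)
    function(newdata) rep(label, n_cohort_rows(newdata))
  }
}
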