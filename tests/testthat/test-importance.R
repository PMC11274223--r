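test_that("combine_importance matches hand-computed aggregation", {
  xgb <- importance_vector(c(a = 2, b = 0), source = "xgb")
  svm <- importance_vector(c(a = 0, b = 1), source = "svm")
  rf <- importance_vector(c(a = 1, b = 1), source = "rf")
  fi <- combine_importance(xgb, svm, rf,
                           weights = c(xgb = 0.01, svm = 0.73, rf = 0.19))
  # (2*0.01 + 0*0.73 + 1*0.19)/0.93 and (0*0.01 + 1*0.73 + 1*0.19)/0.93
  expect_equal(unname(fi$scores["a"]), 0.21 / 0.93, tolerance = 1e-12)
  expect_equal(unname(fi$scores["b"]), 0.92 / 0.93, tolerance = 1e-12)
})

test_that("aggregation fixed points and degenerate weights", {
  v <- c(a = 0.3, b = 1.2, c = 0)
  iv <- function(src) importance_vector(v, source = src)
  fi <- combine_importance(iv("xgb"), iv("svm"), iv("rf"),
                           weights = c(0.2, 0.5, 0.1))
  expect_equal(fi$scores, abs(v)) # equal inputs -> identity

  one_hot <- combine_importance(
    importance_vector(c(a = 9, b = 1, c = 2)),
    iv("svm"), iv("rf"), weights = c(1, 0, 0))
  expect_equal(unname(one_hot$scores), c(9, 1, 2))
})

test_that("aggregation is a convex combination and weight-scale invariant", {
  set.seed(77)
  for (i in 1:50) {
    sc <- function() stats::setNames(rnorm(6), letters[1:6])
    x <- importance_vector(sc()); s <- importance_vector(sc())
    r <- importance_vector(sc())
    w <- runif(3)
    fi <- combine_importance(x, s, r, weights = w)
    lo <- pmin(x$scores, s$scores, r$scores)
    hi <- pmax(x$scores, s$scores, r$scores)
    expect_true(all(fi$scores >= lo - 1e-12 & fi$scores <= hi + 1e-12))
    fi_scaled <- combine_importance(x, s, r, weights = 7.3 * w)
    expect_equal(fi$scores, fi_scaled$scores, tolerance = 1e-12)
  }
})

test_that("mismatched feature sets are reported", {
  a <- importance_vector(c(a = 1, b = 2))
  b <- importance_vector(c(a = 1, c = 2))
  expect_error(combine_importance(a, b, a), "c")
  expect_error(combine_importance(a, a, a, weights = c(0, 0, 0)),
               "positive sum")
})

test_that("rank_features sorts descending with alphabetical tie-break", {
  expect_equal(rank_features(importance_vector(c(a = 0.2, b = 0.5))),
               c("b", "a"))
  expect_equal(rank_features(importance_vector(c(b = 0.3, a = 0.3))),
               c("a", "b"))
  set.seed(3)
  v <- stats::setNames(runif(20), paste0("f", sprintf("%02d", 1:20)))
  ranked <- rank_features(importance_vector(v))
  # independent re-sort oracle
  oracle <- names(sort(v, decreasing = TRUE))
  expect_equal(ranked, oracle)
})

test_that("random-forest importance separates a decisive feature from noise", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    a <- rnorm(n)
    y <- factor(ifelse(a > 0.6, "SGA", ifelse(a < -0.6, "LGA", "AGA")),
                levels = c("AGA", "LGA", "SGA"))
    x <- cbind(a = a, b = rnorm(n))
    fit <- fit_base_learner(fast_rf_spec(80, seed = s), x, y)
    imp <- extract_importance(fit)
    if (imp$scores[["a"]] > imp$scores[["b"]]) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("gradient-boosting importance covers unused features with zero", {
  co <- signal_cohort(n = 150)
  fit <- fit_base_learner(
    base_learner_spec("gradient-boosted-trees",
                      list(nrounds = 20, eta = 0.3, max_depth = 2)),
    feature_matrix(co), cohort_outcome(co))
  imp <- extract_importance(fit)
  expect_setequal(names(imp$scores), names(cohort_data(co)))
  expect_true(all(imp$scores >= 0))
  expect_equal(sum(imp$scores), 1, tolerance = 1e-6) # gains sum to 1
})

test_that("one-vs-one linear SVM importance favours the separating feature", {
  set.seed(9)
  n <- 120
  a <- c(rnorm(n / 3, -2), rnorm(n / 3, 0), rnorm(n / 3, 2))
  x <- cbind(a = a, b = rnorm(n))
  y <- factor(rep(c("AGA", "LGA", "SGA"), each = n / 3))
  imp <- svm_ovo_importance(x, y)
  expect_identical(names(imp$scores), c("a", "b"))
  expect_gt(imp$scores[["a"]], imp$scores[["b"]])
  expect_match(imp$normalization, "one-vs-one")

  # the support-vector path of extract_importance delegates here
  fit <- fit_base_learner(base_learner_spec("support-vector",
                                            list(kernel = "radial")), x, y)
  imp2 <- extract_importance(fit, x = x, y = y)
  expect_equal(imp2$scores, imp$scores)
  expect_error(extract_importance(fit), "training data")
})

test_that("combined ensemble importance runs end to end and stays bounded", {
  co <- signal_cohort(n = 150)
  cfg <- ensemble_config(
    theta = 0.001, weights = c(0.19, 0.01, 0.73),
    learners = list(
      c0 = fast_rf_spec(60),
      c1 = base_learner_spec("gradient-boosted-trees",
                             list(nrounds = 20, eta = 0.3)),
      c2 = base_learner_spec("support-vector", list(kernel = "radial"))))
  fit <- fit_wivela(co, cfg)
  fi <- wivela_importance(fit, co)
  expect_setequal(names(fi$scores), names(cohort_data(co)))
  expect_true(all(fi$scores >= 0))
  expect_equal(fi$source, "combined")
})
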