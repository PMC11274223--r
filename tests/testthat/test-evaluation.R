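test_that("stratified split preserves class proportions and partitions rows", {
  set.seed(10)
  df <- tibble::tibble(x = rnorm(100))
  co <- cohort_table(df, cohort_schema(column_meta("x", "continuous")),
                     outcome = c(rep("AGA", 80), rep("LGA", 10),
                                 rep("SGA", 10)))
  sp <- stratified_split(co, 0.25, seed = 4)
  counts <- table(cohort_outcome(sp$test))
  expect_equal(unname(counts[["AGA"]]), 20L)
  expect_true(counts[["LGA"]] %in% 2:3)
  expect_true(counts[["SGA"]] %in% 2:3)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- stratified_split(co, 0.25, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("a perfect classifier stub scores accuracy 1 and MSE 0", {
  co <- signal_cohort(n = 90)
  oracle_factory <- function(train) {
    function(newdata) as.character(cohort_outcome(newdata))
  }
  cv <- repeated_cv(co, oracle_factory, folds = 3, repeats = 2, seed = 1)
  expect_equal(cv$summary$mean_acc, 1)
  expect_equal(cv$summary$mean_neg_mse, 0)
  expect_equal(nrow(cv$folds), 6)  # folds x repeats rows recorded
})

test_that("a majority-class stub matches the analytic expectation", {
  set.seed(8)
  df <- tibble::tibble(x = rnorm(1000))
  co <- cohort_table(df, cohort_schema(column_meta("x", "continuous")),
                     outcome = sample(rep(c("AGA", "LGA", "SGA"),
                                          c(830, 117, 53))))
  cv <- repeated_cv(co, constant_factory("AGA"), folds = 10, repeats = 2,
                    seed = 3)
  expect_lt(abs(cv$summary$mean_acc - 0.83), 0.01)
  # MSE of always answering code 0: LGA contributes 1^2, SGA 2^2
  expect_lt(abs(-cv$summary$mean_neg_mse - (0.117 + 4 * 0.053)), 0.05)
})

test_that("two-fold metrics of a deterministic stub replay by hand", {
  # 8 rows, 4/2/2; every stratified 2-fold split holds out 2 AGA, 1 LGA,
  # 1 SGA: accuracy 2/4, MSE (0 + 0 + 1 + 4)/4 regardless of the draw.
  df <- tibble::tibble(x = as.double(1:8))
  co <- cohort_table(df, cohort_schema(column_meta("x", "continuous")),
                     outcome = c(rep("AGA", 4), rep("LGA", 2),
                                 rep("SGA", 2)))
  cv <- repeated_cv(co, constant_factory("AGA"), folds = 2, repeats = 2,
                    seed = 5)
  expect_equal(cv$folds$accuracy, rep(0.5, 4))
  expect_equal(cv$folds$mse, rep(1.25, 4))
  expect_equal(cv$summary$std_acc, 0)
})

test_that("repeated_cv reproduces under a fixed seed and guards stratification", {
  co <- signal_cohort(n = 90)
  c1 <- repeated_cv(co, rf_factory(40), folds = 3, repeats = 1, seed = 2)
  c2 <- repeated_cv(co, rf_factory(40), folds = 3, repeats = 1, seed = 2)
  expect_identical(c1$folds, c2$folds)
  expect_error(repeated_cv(co, rf_factory(40), folds = 60, repeats = 1,
                           seed = 1),
               "fewer than folds")
})

test_that("classification report matches hand computation", {
  enc <- class_encoding(c("A", "B", "C"))
  # class C never occurs, so its metrics are zero-division -> flagged
  expect_warning(
    rep1 <- classification_report(c("A", "A", "B"), c("A", "B", "B"),
                                  enc = enc),
    "zero-division")
  expect_equal(rep1$per_class$precision[1:2], c(1, 0.5))
  expect_equal(rep1$per_class$recall[1:2], c(0.5, 1))
  expect_equal(rep1$accuracy, 2 / 3)
  expect_equal(unname(rep1$confusion["A", "B"]), 1)
  expect_equal(sum(diag(rep1$confusion)) / sum(rep1$confusion),
               rep1$accuracy)
  # row sums equal class supports
  expect_equal(unname(rowSums(rep1$confusion)),
               rep1$per_class$support)
})

test_that("perfect predictions give all-one metrics; degenerate input warns", {
  truth <- c("AGA", "LGA", "SGA", "AGA")
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 3))
  expect_false(perfect$zero_division)

  expect_warning(
    single <- classification_report(rep("AGA", 5), rep("AGA", 5)),
    "zero-division")
  expect_equal(single$accuracy, 1)
  expect_equal(single$per_class$f1[single$per_class$class != "AGA"],
               c(0, 0))
  expect_error(classification_report("AGA", "XGA"), "outside the encoding")
})

test_that("cv_compare scores ensemble and bases on identical folds", {
  co <- signal_cohort(n = 150)
  res <- cv_compare(co, fast_ensemble_config(), folds = 3, repeats = 1,
                    seed = 6)
  expect_equal(res$model, c("wivela", "c0", "c1", "c2"))
  expect_true(all(res$mean_acc >= 0 & res$mean_acc <= 1))
  expect_true(all(res$mean_neg_mse <= 0))
  res2 <- cv_compare(co, fast_ensemble_config(), folds = 3, repeats = 1,
                     seed = 6)
  expect_identical(res, res2)
})
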