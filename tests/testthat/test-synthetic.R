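test_that("exact generation realizes class counts by largest remainder", {
  gen <- generate_cohort(synthetic_spec(
    n_rows = 1000, prevalences = c(SGA = 0.0533, LGA = 0.1168,
                                   AGA = 0.8299),
    features = list(feature_spec("x", "continuous", base = 0)),
    seed = 1))
  counts <- table(cohort_outcome(gen$cohort))
  expect_equal(sum(counts), 1000)
  # fractions 53.3 / 116.8 / 829.9 -> 53 / 117 / 830
  expect_equal(as.integer(counts[c("SGA", "LGA", "AGA")]),
               c(53L, 117L, 830L))
})

test_that("generation is deterministic: same seed, byte-identical CSV", {
  spec <- sga_lga_synthetic_spec(n_rows = 400, seed = 33)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec)$cohort, p1)
  write_cohort(generate_cohort(spec)$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted rows are exactly the ones preprocessing removes", {
  gen <- generate_cohort(sga_lga_synthetic_spec(n_rows = 600,
                                                n_duplicates = 7,
                                                n_invalid = 5, seed = 2))
  expect_length(gen$truth$duplicate_rows, 7)
  expect_length(gen$truth$invalid_rows, 5)
  co <- build_outcome(gen$cohort)
  res <- remove_duplicates_and_invalid(co)
  expect_equal(res$report$n_duplicates_removed, 7L)
  expect_equal(res$report$n_invalid_removed, 5L)
  removed <- setdiff(seq_len(600),
                     sort(c(gen$truth$duplicate_rows,
                            gen$truth$invalid_rows)))
  expect_equal(n_cohort_rows(res$cohort), length(removed))
  # each planted duplicate equals its recorded source row
  d <- cohort_data(gen$cohort)
  for (i in seq_along(gen$truth$duplicate_rows)) {
    expect_equal(d[gen$truth$duplicate_rows[i], ],
                 d[gen$truth$duplicate_sources[i], ],
                 ignore_attr = TRUE)
  }
})

test_that("without missingness or planted rows, cleaning is the identity", {
  gen <- generate_cohort(toy_cohort_spec(n_rows = 200, seed = 5))
  res <- remove_duplicates_and_invalid(gen$cohort)
  expect_equal(res$report$n_retained, 200L)
  expect_identical(cohort_data(res$cohort), cohort_data(gen$cohort))
  expect_equal(sum(is.na(cohort_data(gen$cohort))), 0)
})

test_that("missingness concentrates where configured", {
  gen <- generate_cohort(sga_lga_synthetic_spec(n_rows = 2000, seed = 12))
  miss <- colSums(is.na(cohort_data(gen$cohort)))
  lipids <- c("tc", "tg", "hdl", "ldl")
  expect_true(all(miss[lipids] / 2000 > 0.10))
  expect_true(all(miss[setdiff(names(miss), c(lipids, "fpg",
                                              paste0("ogtt_", c("0h", "1h", "2h"))))] == 0))
})

test_that("an infeasible spec is rejected", {
  expect_error(synthetic_spec(
    n_rows = 10, features = list(feature_spec("x", "continuous")),
    n_duplicates = 6, n_invalid = 6), "fewer than n_rows")
  expect_error(synthetic_spec(
    n_rows = 10, prevalences = c(SGA = 0.5, LGA = 0.4, AGA = 0.4),
    features = list(feature_spec("x", "continuous"))), "sum to 1")
})

test_that("a null cohort drives a classifier to the majority rate", {
  accs <- vapply(1:10, function(s) {
    gen <- generate_cohort(toy_cohort_spec(
      n_rows = 300, shift = 0,
      prevalences = c(SGA = 0.1, LGA = 0.15, AGA = 0.75),
      seed = 300 + s))
    cv <- repeated_cv(gen$cohort,
                      function(tr) fit_base_learner(
                        base_learner_spec("k-nearest-neighbors",
                                          list(k = 25), seed = s),
                        feature_matrix(tr), cohort_outcome(tr)),
                      folds = 3, repeats = 1, seed = s)
    cv$summary$mean_acc
  }, double(1))
  expect_lt(abs(mean(accs) - 0.75), 0.03)
})

test_that("labels are independent of noise features in a signal cohort", {
  gen <- generate_cohort(toy_cohort_spec(n_rows = 800, n_informative = 2,
                                         n_noise = 20, shift = 1.5,
                                         seed = 6))
  y <- cohort_outcome(gen$cohort)
  noise_cols <- grep("^noise", names(cohort_data(gen$cohort)),
                     value = TRUE)
  pvals <- vapply(noise_cols, function(nm) {
    stats::kruskal.test(cohort_data(gen$cohort)[[nm]], y)$p.value
  }, double(1))
  # association p-values over noise features behave uniformly
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # while informative features associate overwhelmingly
  p_inf <- stats::kruskal.test(cohort_data(gen$cohort)$inf01, y)$p.value
  expect_lt(p_inf, 1e-10)
})
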