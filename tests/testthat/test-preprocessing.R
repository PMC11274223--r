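test_that("duplicate rows collapse to first occurrence and removal is idempotent", {
  base <- tibble::tibble(age = as.double(1:10), hdl = as.double(10:1),
                         flag = rep(c(0, 1), 5))
  base[3, ] <- base[1, ]
  base[7, ] <- base[1, ]
  co <- cohort_table(base, tiny_schema())
  res <- remove_duplicates_and_invalid(co)
  expect_equal(res$report$n_duplicates_removed, 2L)
  expect_equal(n_cohort_rows(res$cohort), 8)
  again <- remove_duplicates_and_invalid(res$cohort)
  expect_equal(again$report$n_duplicates_removed, 0L)
  expect_equal(cohort_data(again$cohort), cohort_data(res$cohort))
})

test_that("rows with missing cells that match are still duplicates", {
  df <- tibble::tibble(age = c(1, 1, 2), hdl = c(NA, NA, 3),
                       flag = c(0, 0, 1))
  res <- remove_duplicates_and_invalid(cohort_table(df, tiny_schema()))
  expect_equal(res$report$n_duplicates_removed, 1L)
})

test_that("out-of-range and unparseable rows are removed as invalid", {
  df <- tibble::tibble(age = c(30, 250, 40), hdl = c(1, 2, 3),
                       flag = c(0, 1, 0))
  co <- cohort_table(df, tiny_schema(),
                     invalid = tibble::tibble(row = 3L, column = "hdl"))
  res <- remove_duplicates_and_invalid(co)
  expect_equal(res$report$n_invalid_removed, 2L)
  expect_equal(cohort_data(res$cohort)$age, 30)
})

test_that("clean input passes through unchanged with zero removals", {
  co <- tiny_cohort()
  res <- remove_duplicates_and_invalid(co)
  expect_equal(cohort_data(res$cohort), cohort_data(co))
  expect_equal(res$report$n_duplicates_removed + res$report$n_invalid_removed,
               0L)
  expect_equal(res$report$n_raw,
               res$report$n_duplicates_removed +
                 res$report$n_invalid_removed + res$report$n_retained)
})

test_that("median imputation fills missing cells and only those", {
  co <- tiny_cohort(age = c(1, 2, NA), hdl = c(1, 2, 4))
  co$data <- tibble::add_row(co$data, age = 4, hdl = 3, flag = 1)
  model <- fit_impute(co)
  expect_equal(unname(model$medians["age"]), 2)
  out <- apply_impute(model, co)
  expect_equal(cohort_data(out)$age, c(1, 2, 2, 4))
  expect_equal(sum(is.na(cohort_data(out))), 0)

  # identity when nothing is missing
  full <- tiny_cohort(hdl = c(1, 2, 3))
  expect_equal(cohort_data(apply_impute(fit_impute(full), full)),
               cohort_data(full))
})

test_that("imputed cells equal independently recomputed column medians", {
  set.seed(31)
  n <- 500
  df <- tibble::as_tibble(stats::setNames(
    lapply(1:5, function(i) {
      v <- rnorm(n)
      v[sample(n, 50)] <- NA
      v
    }), paste0("c", 1:5)))
  schema <- do.call(cohort_schema,
                    lapply(paste0("c", 1:5), column_meta,
                           kind = "continuous"))
  co <- cohort_table(df, schema)
  out <- apply_impute(fit_impute(co), co)
  for (nm in names(df)) {
    obs <- sort(df[[nm]][!is.na(df[[nm]])])
    m <- length(obs)
    med <- if (m %% 2 == 1) obs[(m + 1) / 2] else
      (obs[m / 2] + obs[m / 2 + 1]) / 2   # median by sorting, by hand
    miss <- is.na(df[[nm]])
    expect_true(all(cohort_data(out)[[nm]][miss] == med))
    expect_identical(cohort_data(out)[[nm]][!miss], df[[nm]][!miss])
  }
})

test_that("a column with no observed value in the fit rows errors by name", {
  co <- tiny_cohort(hdl = c(NA, NA, NA))
  expect_error(fit_impute(co), "hdl")
})

test_that("standardization uses the population-sd convention", {
  co <- tiny_cohort(age = c(0, 10), hdl = c(1, 2), flag = c(0, 1))
  scaled <- apply_scaler(fit_scaler(co), co)
  expect_equal(cohort_data(scaled)$age, c(-1, 1))  # sd_n = 5, mean 5
  expect_equal(cohort_data(scaled)$flag, c(0, 1))  # binary untouched

  # refitting on already-standardized data is (numerically) the identity
  rescaled <- apply_scaler(fit_scaler(scaled), scaled)
  expect_equal(cohort_data(rescaled)$age, cohort_data(scaled)$age,
               tolerance = 1e-9)

  # scaled columns have mean 0, population sd 1 on the fit rows
  set.seed(2)
  co2 <- tiny_cohort(age = rnorm(3, 50, 9), hdl = rnorm(3))
  co2$data$hdl[2] <- 0.5
  s2 <- apply_scaler(fit_scaler(co2), co2)
  v <- cohort_data(s2)$age
  expect_equal(mean(v), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
})

test_that("constant columns are centred with scale clamped to 1", {
  co <- tiny_cohort(age = c(7, 7, 7), hdl = c(1, 2, 3))
  scaled <- apply_scaler(fit_scaler(co), co)
  expect_equal(cohort_data(scaled)$age, c(0, 0, 0))
})

test_that("scaler refuses missing values", {
  expect_error(fit_scaler(tiny_cohort()), "missing")
})
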