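#' Feature-importance threshold sweep
#'
#' Takes a feature-importance vector, converts scores to absolute values,
#' sorts them in descending order, and treats each distinct score as an
#' inclusion threshold: row *r* of the sweep keeps the features with
#' `|score| >= threshold_r`, so the feature sets along the sweep are
#' nested and non-decreasing in size. Each feature subset is scored by
#' repeated stratified k-fold cross-validation of the supplied
#' classifier; the table records mean accuracy, its standard deviation,
#' and the accuracy change against the previous row (`delta_acc`; the
#' first row's delta is its own mean accuracy).
#'
#' Duplicate scores collapse to a single threshold. An all-zero
#' importance vector yields a single row containing all features.
#'
#' @param x A labelled `cohort_table` covering all scored features.
#' @param model_factory `function(train_cohort)` returning a fitted
#'   object accepted by `predict_fn` of [repeated_cv()]; it is refitted
#'   on each fold restricted to the candidate features.
#' @param importance An [importance_vector()] covering the candidate
#'   features.
#' @param folds,repeats Cross-validation protocol (`folds >= 2`,
#'   `repeats >= 1`).
#' @param seed Base seed; repeat `r` of every row uses `seed + r`, so the
#'   sweep is reproducible bit-for-bit.
#' @return A `sweep_table` tibble: one row per threshold with columns
#'   `threshold`, `n_features`, `features` (list column), `mean_acc`,
#'   `std_acc`, `delta_acc`.
#' @export
feature_sweep <- function(x, model_factory, importance,
                          folds = 10L, repeats = 10L, seed = 1L) {
  stopifnot(inherits(importance, "importance_vector"),
            folds >= 2, repeats >= 1)
  scores <- abs(importance$scores)
  absent <- setdiff(names(scores), names(cohort_data(x)))
  if (length(absent)) {
    stop("cohort lacks scored feature(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ord <- rank_features(importance)
  thresholds <- sort(unique(unname(scores)), decreasing = TRUE)
  if (all(scores == 0)) thresholds <- 0

  rows <- lapply(seq_along(thresholds), function(r) {
    thr <- thresholds[r]
    feats <- ord[scores[ord] >= thr]
    sub <- select_features(x, feats)
    cv <- repeated_cv(sub, model_factory, folds = folds,
                      repeats = repeats, seed = seed)
    tibble::tibble(threshold = thr, n_features = length(feats),
                   features = list(feats),
                   mean_acc = cv$summary$mean_acc,
                   std_acc = cv$summary$std_acc)
  })
  out <- dplyr::bind_rows(rows)
  out$delta_acc <- c(out$mean_acc[1], diff(out$mean_acc))
  class(out) <- c("sweep_table", class(out))
  out
}

#' Select the best feature group from a sweep table
#'
#' Orders the sweep rows by mean accuracy (descending), then standard
#' deviation (ascending), then feature count (ascending), and returns the
#' feature list of the first row. An optional tolerance `tol` treats mean
#' accuracies within `tol` of the maximum as equal before ordering, which
#' lets a smaller, steadier feature group win over a marginally more
#' accurate larger one.
#'
#' @param sweep A `sweep_table` from [feature_sweep()].
#' @param tol Accuracy tolerance (default 0: strict ordering).
#' @return Character vector of selected feature names.
#' @export
select_best <- function(sweep, tol = 0) {
  stopifnot(nrow(sweep) > 0, tol >= 0)
  acc <- sweep$mean_acc
  acc_key <- if (tol > 0) {
    ifelse(acc >= max(acc) - tol, max(acc), acc)
  } else {
    acc
  }
  ord <- order(-acc_key, sweep$std_acc, sweep$n_features)
  sweep$features[[ord[1]]]
}
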