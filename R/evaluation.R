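#' Stratified train/test split
#'
#' Samples `test_fraction` of each class (rounded to the nearest integer,
#' at least 1) into the test set, so class proportions are preserved
#' within one sample per class.
#'
#' @param x A labelled `cohort_table`.
#' @param test_fraction Fraction of each class sent to the test set.
#' @param seed Integer seed.
#' @return A list with `train` and `test` cohort tables and the integer
#'   index vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(x, test_fraction = 0.25, seed = 1L) {
  y <- cohort_outcome(x)
  if (is.null(y)) stop("split needs a labelled cohort", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  test_idx <- integer()
  for (cl in names(counts)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = subset_rows(x, train_idx),
       test = subset_rows(x, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has ", length(idx),
           " samples, fewer than folds = ", folds, call. = FALSE)
    }
    assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat a fresh stratified fold assignment is drawn with seed
#' `seed + repeat`; the model factory is fitted on the training folds and
#' scored on the held-out fold by accuracy and mean squared error on
#' integer-encoded labels (so "negative MSE" is comparable across
#' models).
#'
#' @param x A labelled `cohort_table`.
#' @param model_factory `function(train_cohort)` returning an object for
#'   which `predict_fn(fitted, newdata_cohort)` yields labels.
#' @param folds,repeats Protocol counts.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param predict_fn Prediction function; the default handles
#'   `wivela_fit` and `base_fit` objects.
#' @return A `cv_report`: list with `folds` (tibble of per-fold metrics),
#'   `summary` (mean/sd of accuracy and negative MSE), and `protocol`.
#' @export
repeated_cv <- function(x, model_factory, folds = 10L, repeats = 10L,
                        seed = 1L, predict_fn = default_predict_fn) {
  y <- cohort_outcome(x)
  if (is.null(y)) stop("cross-validation needs a labelled cohort",
                       call. = FALSE)
  stopifnot(folds >= 2, repeats >= 1)
  rows <- list()
  for (r in seq_len(repeats)) {
    assignment <- stratified_folds(y, folds, seed + r)
    for (f in seq_len(folds)) {
      test_idx <- which(assignment == f)
      fitted <- model_factory(subset_rows(x, -test_idx))
      pred <- predict_fn(fitted, subset_rows(x, test_idx))
      truth <- y[test_idx]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = r, fold = f,
        accuracy = mean(as.character(pred) == as.character(truth)),
        mse = mean((encode_labels(pred, x$enc) -
                      encode_labels(truth, x$enc))^2))
    }
  }
  fold_tbl <- dplyr::bind_rows(rows)
  structure(list(
    folds = fold_tbl,
    summary = tibble::tibble(
      mean_acc = mean(fold_tbl$accuracy),
      std_acc = stats::sd(fold_tbl$accuracy),
      mean_neg_mse = mean(-fold_tbl$mse),
      std_neg_mse = stats::sd(fold_tbl$mse)),
    protocol = list(folds = folds, repeats = repeats, seed = seed,
                    encoding = x$enc$labels)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_report> %d x %d-fold CV: mean acc %.4f (sd %.4f), neg MSE %.4f (sd %.4f)\n",
    x$protocol$repeats, x$protocol$folds,
    s$mean_acc, s$std_acc, s$mean_neg_mse, s$std_neg_mse))
  invisible(x)
}

default_predict_fn <- function(fitted, newdata) {
  if (inherits(fitted, "wivela_fit")) {
    predict(fitted, newdata)$labels
  } else if (inherits(fitted, "base_fit")) {
    predict_label(fitted, feature_matrix(newdata, fitted$features))
  } else if (is.function(fitted)) {
    fitted(newdata)
  } else {
    stop("no default prediction method for class ",
         paste(class(fitted), collapse = "/"), call. = FALSE)
  }
}

#' Confusion matrix and per-class classification report
#'
#' Standard definitions: per-class precision, recall, F1 and support, the
#' overall accuracy (= trace of the confusion matrix over n), and macro /
#' support-weighted averages. A zero denominator yields 0 and sets the
#' `zero_division` flag with a warning.
#'
#' @param truth,pred Equal-length label vectors.
#' @param enc Class encoding fixing the class order.
#' @return A `classification_report` object.
#' @export
classification_report <- function(truth, pred, enc = class_encoding()) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  bad <- setdiff(unique(c(truth, pred)), enc$labels)
  if (length(bad)) {
    stop("label(s) outside the encoding: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lv <- enc$labels
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  names(dimnames(cm)) <- c("truth", "pred")
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  zero_division <- any(pred_n == 0 & support > 0) | any(support == 0)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  if (zero_division) {
    warning("zero-division in precision/recall set to 0", call. = FALSE)
  }
  n <- sum(cm)
  per_class <- tibble::tibble(class = lv, precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1),
                              support = as.integer(support))
  structure(list(
    confusion = cm,
    per_class = per_class,
    accuracy = sum(tp) / n,
    macro_avg = c(precision = mean(precision), recall = mean(recall),
                  f1 = mean(f1)),
    weighted_avg = c(precision = sum(precision * support) / n,
                     recall = sum(recall * support) / n,
                     f1 = sum(f1 * support) / n),
    zero_division = zero_division
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\n")
  df <- as.data.frame(x$per_class)
  df[2:4] <- lapply(df[2:4], function(v) sprintf("%.2f", v))
  print(df, row.names = FALSE)
  cat(sprintf("\naccuracy     %.2f  (n = %d)\n", x$accuracy,
              sum(x$per_class$support)))
  cat(sprintf("macro avg    %.2f %.2f %.2f\n", x$macro_avg[1],
              x$macro_avg[2], x$macro_avg[3]))
  cat(sprintf("weighted avg %.2f %.2f %.2f\n", x$weighted_avg[1],
              x$weighted_avg[2], x$weighted_avg[3]))
  invisible(x)
}

#' Compare the ensemble with its base learners on identical folds
#'
#' Runs one repeated stratified cross-validation and, in each fold, fits
#' the three configured base learners once: the ensemble prediction and
#' each learner's own argmax prediction are then scored on the same
#' held-out samples, so all accuracies are computed on identical folds.
#'
#' @param x A labelled `cohort_table`.
#' @param config An [ensemble_config()].
#' @param folds,repeats,seed Protocol.
#' @return A tibble with one row per model (`wivela`, `c0`, `c1`, `c2`)
#'   and columns `mean_acc`, `std_acc`, `mean_neg_mse`, `std_neg_mse`.
#' @export
cv_compare <- function(x, config = ensemble_config(), folds = 10L,
                       repeats = 10L, seed = 1L) {
  y <- cohort_outcome(x)
  if (is.null(y)) stop("cross-validation needs a labelled cohort",
                       call. = FALSE)
  models <- c("wivela", "c0", "c1", "c2")
  acc <- mse <- stats::setNames(
    replicate(length(models), numeric(0), simplify = FALSE), models)
  for (r in seq_len(repeats)) {
    assignment <- stratified_folds(y, folds, seed + r)
    for (f in seq_len(folds)) {
      test_idx <- which(assignment == f)
      fit <- fit_wivela(subset_rows(x, -test_idx), config)
      pred <- predict(fit, subset_rows(x, test_idx))
      truth_code <- encode_labels(y[test_idx], x$enc)
      labs <- list(
        wivela = pred$labels,
        c0 = fit$levels[max.col(pred$blocks$c0, ties.method = "first")],
        c1 = fit$levels[max.col(pred$blocks$c1, ties.method = "first")],
        c2 = fit$levels[max.col(pred$blocks$c2, ties.method = "first")])
      for (m in models) {
        code <- encode_labels(labs[[m]], x$enc)
        acc[[m]] <- c(acc[[m]], mean(code == truth_code))
        mse[[m]] <- c(mse[[m]], mean((code - truth_code)^2))
      }
    }
  }
  dplyr::bind_rows(lapply(models, function(m) tibble::tibble(
    model = m,
    mean_acc = mean(acc[[m]]), std_acc = stats::sd(acc[[m]]),
    mean_neg_mse = mean(-mse[[m]]), std_neg_mse = stats::sd(mse[[m]]))))
}
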