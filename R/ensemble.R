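#' Ensemble configuration for the gated voting classifier
#'
#' The classifier fits a primary learner `c0` and two secondary learners
#' `c1`, `c2`. At prediction time each sample whose maximum `c0` class
#' probability is at least `1 - theta` *inherits* `c0`'s prediction; the
#' remaining (uncertain) samples are decided by weighted voting over all
#' three learners. The reported optimum for the obstetric cohort this
#' design targets is `theta = 0.001` with weights
#' `(0.19, 0.01, 0.73)` over (random forest, gradient boosting, SVM).
#'
#' @param theta Confidence-gate width in `[0, 1]`; `theta = 1` inherits
#'   everything (pure primary classifier), `theta = 0` inherits only
#'   samples predicted with probability exactly 1.
#' @param weights Numeric length-3 vector `(w_c0, w_c1, w_c2)`, each
#'   `>= 0`, at least one positive. Not renormalized: the argmax of the
#'   vote is scale-invariant.
#' @param learners Named list of three [base_learner_spec()]s:
#'   `c0` (primary), `c1`, `c2`.
#' @param voting `"soft"` (probability-weighted sum, default) or `"hard"`
#'   (weighted one-hot votes).
#' @return An `ensemble_config` object.
#' @export
ensemble_config <- function(theta = 0.001,
                            weights = c(0.19, 0.01, 0.73),
                            learners = NULL,
                            voting = c("soft", "hard")) {
  voting <- match.arg(voting)
  if (is.null(learners)) {
    specs <- default_learner_specs()
    learners <- list(c0 = specs$rf, c1 = specs$xgb, c2 = specs$svm)
  }
  stopifnot(length(theta) == 1, theta >= 0, theta <= 1)
  weights <- as.double(weights)
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be 3 non-negative values with a positive sum",
         call. = FALSE)
  }
  if (!identical(sort(names(learners)), c("c0", "c1", "c2"))) {
    stop("learners must be a named list with entries c0, c1, c2",
         call. = FALSE)
  }
  for (l in learners) stopifnot(inherits(l, "base_learner_spec"))
  names(weights) <- c("c0", "c1", "c2")
  structure(list(theta = theta, weights = weights,
                 learners = learners[c("c0", "c1", "c2")], voting = voting),
            class = "ensemble_config")
}

#' Fit the gated voting ensemble
#'
#' Fits the three base learners on identical training rows.
#'
#' @param train A labelled `cohort_table` with no missing values, or a
#'   numeric matrix (then supply `y`).
#' @param config An [ensemble_config()].
#' @param y Factor of labels when `train` is a matrix.
#' @param features Optional character vector restricting the feature set.
#' @return A `wivela_fit` object.
#' @export
fit_wivela <- function(train, config = ensemble_config(), y = NULL,
                       features = NULL) {
  if (inherits(train, "cohort_table")) {
    y <- cohort_outcome(train)
    if (is.null(y)) stop("training cohort has no outcome", call. = FALSE)
    x <- feature_matrix(train, features)
    levels_enc <- train$enc$labels
  } else {
    x <- as.matrix(train)
    if (!is.null(features)) x <- x[, features, drop = FALSE]
    if (is.null(y)) stop("supply y when train is a matrix", call. = FALSE)
    levels_enc <- levels(as.factor(y))
  }
  y <- factor(as.character(y), levels = intersect(levels_enc,
                                                  unique(as.character(y))))
  fits <- lapply(config$learners, fit_base_learner, x = x, y = y)
  structure(list(config = config, fits = fits, levels = levels(y),
                 features = colnames(x)),
            class = "wivela_fit")
}

#' @export
print.wivela_fit <- function(x, ...) {
  kinds <- vapply(x$config$learners, `[[`, "", "kind")
  cat("<wivela_fit> theta=", x$config$theta,
      ", weights=(", paste(x$config$weights, collapse = ", "), ")\n",
      "  learners: ", paste(sprintf("%s=%s", names(kinds), kinds),
                            collapse = ", "), "\n",
      "  classes: ", paste(x$levels, collapse = ", "),
      "; features: ", length(x$features), "\n", sep = "")
  invisible(x)
}

#' Confidence gate over the primary classifier's probabilities
#'
#' A sample is *inherited* (the primary classifier's prediction is kept)
#' when its maximum class probability is at least `1 - theta`; the
#' comparison is closed (`>=`).
#'
#' @param pc0 Probability matrix of the primary classifier (rows sum
#'   to 1).
#' @param theta Gate width in `[0, 1]`.
#' @return Logical vector, `TRUE` = inherited, `FALSE` = goes to voting.
#' @export
gate_mask <- function(pc0, theta) {
  stopifnot(theta >= 0, theta <= 1)
  apply(as.matrix(pc0), 1, max) >= 1 - theta
}

#' Weighted voting over aligned probability blocks
#'
#' Soft voting scores each class by `sum_k w_k * p_k[i, c]`; hard voting
#' first reduces each block to a one-hot argmax vote and then weights.
#' Ties are broken towards the lowest class index (the encoding order).
#'
#' @param blocks List of probability matrices aligned on the same samples
#'   and class columns.
#' @param weights Numeric vector, one weight per block.
#' @param voting `"soft"` or `"hard"`.
#' @param levels Class labels in column order (default: colnames of the
#'   first block).
#' @return Factor of voted labels.
#' @export
weighted_vote <- function(blocks, weights, voting = c("soft", "hard"),
                          levels = colnames(blocks[[1]])) {
  voting <- match.arg(voting)
  stopifnot(length(blocks) == length(weights))
  dims <- unique(lapply(blocks, dim))
  if (length(dims) != 1) stop("probability blocks are misaligned",
                              call. = FALSE)
  n <- dims[[1]][1]; k <- dims[[1]][2]
  if (n == 0) return(factor(character(), levels = levels))
  score <- matrix(0, n, k)
  for (b in seq_along(blocks)) {
    p <- as.matrix(blocks[[b]])
    if (voting == "hard") {
      hot <- matrix(0, n, k)
      hot[cbind(seq_len(n), max.col(p, ties.method = "first"))] <- 1
      p <- hot
    }
    score <- score + weights[[b]] * p
  }
  factor(levels[max.col(score, ties.method = "first")], levels = levels)
}

#' Predict with the gated voting ensemble
#'
#' Returns the predicted labels together with a full audit trail: the
#' gate mask and the three per-learner probability blocks, from which the
#' prediction can be recomposed exactly (inherited samples take the
#' primary argmax; voting samples take the weighted vote).
#'
#' @param object A `wivela_fit`.
#' @param newdata A `cohort_table` or numeric matrix with the training
#'   columns.
#' @param ... Unused.
#' @return A list with `labels` (factor), `inherited` (logical gate
#'   mask), and `blocks` (named list `c0`, `c1`, `c2` of probability
#'   matrices).
#' @export
predict.wivela_fit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cohort_table")) {
    feature_matrix(newdata, object$features)
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m))) {
      if (!all(object$features %in% colnames(m))) {
        stop("newdata lacks training column(s): ",
             paste(setdiff(object$features, colnames(m)), collapse = ", "),
             call. = FALSE)
      }
      m <- m[, object$features, drop = FALSE]
    }
    m
  }
  blocks <- lapply(object$fits, predict_prob, x = x)
  cfg <- object$config
  inherited <- gate_mask(blocks$c0, cfg$theta)
  labels <- factor(rep(NA_character_, nrow(x)), levels = object$levels)
  if (any(inherited)) {
    p0 <- blocks$c0[inherited, , drop = FALSE]
    labels[inherited] <-
      object$levels[max.col(p0, ties.method = "first")]
  }
  if (any(!inherited)) {
    vb <- lapply(blocks, function(p) p[!inherited, , drop = FALSE])
    labels[!inherited] <- weighted_vote(vb, cfg$weights, cfg$voting,
                                        levels = object$levels)
  }
  list(labels = labels, inherited = inherited, blocks = blocks)
}
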