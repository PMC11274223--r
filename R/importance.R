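#' Importance vector
#'
#' Per-feature non-negative relevance scores from one learner, or from
#' the weighted aggregation.
#'
#' @param scores Named numeric vector (feature -> score), all `>= 0`
#'   after the absolute-value step.
#' @param source One of `"rf"`, `"xgb"`, `"svm"`, `"combined"`.
#' @param normalization Free-text note on the convention used.
#' @return An `importance_vector` object.
#' @export
importance_vector <- function(scores, source = "combined",
                              normalization = NA_character_) {
  scores <- abs(scores)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("importance scores must be named by feature", call. = FALSE)
  }
  structure(list(scores = scores, source = source,
                 normalization = normalization),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat("<importance_vector> source=", x$source, ", ",
      length(x$scores), " features\n", sep = "")
  print(utils::head(sort(x$scores, decreasing = TRUE), 10))
  invisible(x)
}

#' Extract per-feature importance from a fitted base learner
#'
#' Conventions per learner kind:
#' \itemize{
#'   \item random forest: mean decrease in impurity (Gini importance) —
#'     the impurity reduction attributed to splits on the feature, summed
#'     over splits and averaged over trees.
#'   \item gradient boosting: total gain attributed to the feature
#'     (features never used get 0).
#'   \item support vector: mean of `|w|` over the one-vs-one linear
#'     classifiers (6 ordered pairs for 3 classes). When the predictive
#'     kernel is non-linear, pairwise *linear-kernel surrogates* are
#'     refitted on the stored training data solely for importance, and
#'     the normalization note records this.
#' }
#'
#' @param fit A `base_fit`. For the support-vector path the training data
#'   must be supplied (or stored) — see `x`, `y`.
#' @param x,y Training matrix and labels, required for the linear
#'   surrogate of a support-vector fit.
#' @param cost SVM cost for the linear surrogates.
#' @return An `importance_vector`.
#' @export
extract_importance <- function(fit, x = NULL, y = NULL, cost = 1) {
  stopifnot(inherits(fit, "base_fit"))
  switch(fit$spec$kind,
    "random-forest" = {
      imp <- randomForest::importance(fit$model, type = 2)[, 1]
      importance_vector(imp[fit$features], source = "rf",
                        normalization = "mean decrease in impurity")
    },
    "gradient-boosted-trees" = {
      tbl <- xgboost::xgb.importance(model = fit$model)
      scores <- stats::setNames(rep(0, length(fit$features)),
                                fit$features)
      scores[tbl$Feature] <- tbl$Gain
      importance_vector(scores, source = "xgb",
                        normalization = "total gain, unused features = 0")
    },
    "support-vector" = {
      if (is.null(x) || is.null(y)) {
        stop("support-vector importance needs the training data (x, y) ",
             "to fit one-vs-one linear surrogates", call. = FALSE)
      }
      svm_ovo_importance(x, y, cost = cost)
    },
    stop("no importance convention for learner kind '", fit$spec$kind,
         "'", call. = FALSE)
  )
}

#' One-vs-one linear SVM coefficient importance
#'
#' Fits a linear-kernel SVM for every unordered class pair, reconstructs
#' the weight vector `w = t(coefs) %*% SV`, and averages `|w|` over the
#' `N(N-1)` ordered one-vs-one classifiers (each unordered pair
#' contributes its mirror twice, so this equals the mean over unordered
#' pairs).
#'
#' @param x Numeric training matrix.
#' @param y Factor of class labels.
#' @param cost SVM cost parameter.
#' @return An `importance_vector` with `source = "svm"`.
#' @export
svm_ovo_importance <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  pairs <- utils::combn(levels(y), 2, simplify = FALSE)
  w_abs <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    fit <- e1071::svm(x = x[idx, , drop = FALSE],
                      y = droplevels(y[idx]),
                      kernel = "linear", cost = cost, scale = FALSE)
    abs(drop(t(fit$coefs) %*% fit$SV))
  })
  scores <- Reduce(`+`, w_abs) / length(w_abs)
  names(scores) <- colnames(x)
  importance_vector(scores, source = "svm",
                    normalization = paste("mean |w| over one-vs-one",
                                          "linear-kernel surrogates"))
}

#' Aggregate per-learner importance with the ensemble weights
#'
#' `fi_i = (|xgb_i| w_xgb + |svm_i| w_svm + |rf_i| w_rf) /
#'         (w_xgb + w_svm + w_rf)` — a convex combination of the
#' absolute per-learner scores, so each aggregated score is bounded by
#' the per-feature min and max of its inputs, and the result is invariant
#' to rescaling all weights by a positive constant.
#'
#' @param xgb,svm,rf `importance_vector`s over identical feature sets.
#' @param weights Numeric length-3 vector `(w_xgb, w_svm, w_rf)`, each
#'   `>= 0`, positive sum.
#' @return An `importance_vector` with `source = "combined"`.
#' @export
combine_importance <- function(xgb, svm, rf,
                               weights = c(xgb = 0.01, svm = 0.73,
                                           rf = 0.19)) {
  for (v in list(xgb, svm, rf)) stopifnot(inherits(v, "importance_vector"))
  weights <- as.double(weights)
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be 3 non-negative values with a positive sum",
         call. = FALSE)
  }
  feats <- names(xgb$scores)
  for (v in list(svm, rf)) {
    if (!setequal(names(v$scores), feats)) {
      diff <- c(setdiff(names(v$scores), feats),
                setdiff(feats, names(v$scores)))
      stop("feature sets differ: ", paste(unique(diff), collapse = ", "),
           call. = FALSE)
    }
  }
  fi <- (abs(xgb$scores[feats]) * weights[1] +
           abs(svm$scores[feats]) * weights[2] +
           abs(rf$scores[feats]) * weights[3]) / sum(weights)
  importance_vector(fi, source = "combined",
                    normalization = sprintf(
                      "weights (xgb, svm, rf) = (%g, %g, %g)",
                      weights[1], weights[2], weights[3]))
}

#' Rank features by importance
#'
#' Descending by score; exact ties broken alphabetically by feature name.
#'
#' @param fi An `importance_vector`.
#' @return Character vector of feature names, most important first.
#' @export
rank_features <- function(fi) {
  stopifnot(inherits(fi, "importance_vector"), length(fi$scores) > 0)
  nm <- names(fi$scores)
  nm[order(-fi$scores, nm)]
}

#' Combined ensemble feature importance
#'
#' Runs the full aggregation for a fitted gated voting ensemble whose
#' learners are (random forest, gradient boosting, SVM): extracts each
#' learner's importance and combines them with the ensemble's voting
#' weights mapped to `(w_xgb, w_svm, w_rf)`.
#'
#' @param fit A `wivela_fit` with learner kinds `c0` = random-forest,
#'   `c1` = gradient-boosted-trees, `c2` = support-vector.
#' @param train The training `cohort_table` (or matrix) used to fit,
#'   needed for the SVM linear surrogate.
#' @param y Labels when `train` is a matrix.
#' @return An `importance_vector` with `source = "combined"`.
#' @export
wivela_importance <- function(fit, train, y = NULL) {
  stopifnot(inherits(fit, "wivela_fit"))
  kinds <- vapply(fit$config$learners, `[[`, "", "kind")
  expected <- c(c0 = "random-forest", c1 = "gradient-boosted-trees",
                c2 = "support-vector")
  if (!identical(kinds[names(expected)], expected)) {
    stop("combined importance expects learners (c0, c1, c2) = ",
         "(random-forest, gradient-boosted-trees, support-vector)",
         call. = FALSE)
  }
  if (inherits(train, "cohort_table")) {
    y <- cohort_outcome(train)
    x <- feature_matrix(train, fit$features)
  } else {
    x <- as.matrix(train)[, fit$features, drop = FALSE]
  }
  rf_imp <- extract_importance(fit$fits$c0)
  xgb_imp <- extract_importance(fit$fits$c1)
  svm_imp <- extract_importance(fit$fits$c2, x = x, y = y)
  w <- fit$config$weights
  combine_importance(xgb_imp, svm_imp, rf_imp,
                     weights = c(xgb = unname(w["c1"]),
                                 svm = unname(w["c2"]),
                                 rf = unname(w["c0"])))
}
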