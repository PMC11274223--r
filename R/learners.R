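#' Base learner specification
#'
#' Declares one of the five supported probabilistic classifiers and its
#' hyperparameters. All kinds satisfy the class-probability contract
#' required by the gated ensemble.
#'
#' Backend mapping and hyperparameters (`params` entries are passed
#' through):
#' \itemize{
#'   \item `"random-forest"`: [randomForest::randomForest()] —
#'     `ntree`, `mtry`, `nodesize`, `maxnodes`, ...
#'   \item `"gradient-boosted-trees"`: [xgboost::xgb.train()] with
#'     `multi:softprob` — `nrounds`, `max_depth`, `eta`,
#'     `min_child_weight`, `colsample_bytree`, `colsample_bylevel`,
#'     `subsample`, ...
#'   \item `"support-vector"`: [e1071::svm()] with `probability = TRUE` —
#'     `kernel`, `cost`, `degree`, `gamma`, ...
#'   \item `"k-nearest-neighbors"`: [caret::knn3()] — `k`.
#'   \item `"decision-tree"`: [rpart::rpart()] — `cp`, `minsplit`,
#'     `maxdepth`, `split` (passed via `parms`), ...
#' }
#'
#' @param kind Learner kind (see above).
#' @param params Named list of hyperparameters.
#' @param seed Integer seed set immediately before fitting.
#' @return A `base_learner_spec` object.
#' @export
base_learner_spec <- function(kind = c("random-forest",
                                       "gradient-boosted-trees",
                                       "support-vector",
                                       "k-nearest-neighbors",
                                       "decision-tree"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.list(params))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "base_learner_spec")
}

#' Default learner specifications
#'
#' Hyperparameters follow the tuned values reported for each algorithm
#' where the R backend has a direct equivalent (KNN `k = 24`, SVM
#' `cost = 100` with a degree-2 polynomial kernel, gradient boosting with
#' `eta = 0.01`, `max_depth = 4`, `min_child_weight = 2`,
#' `colsample_bytree = 0.5`, `colsample_bylevel = 0.6`, 1000 rounds);
#' parameters without an R equivalent (impurity criterion names,
#' random-forest depth caps) fall back to backend defaults.
#'
#' @param seed Integer seed.
#' @return A named list of [base_learner_spec()] objects
#'   (`rf`, `xgb`, `svm`, `knn`, `cart`).
#' @export
default_learner_specs <- function(seed = 1L) {
  list(
    rf  = base_learner_spec("random-forest",
                            params = list(ntree = 500), seed = seed),
    xgb = base_learner_spec("gradient-boosted-trees",
                            params = list(nrounds = 1000, eta = 0.01,
                                          max_depth = 4,
                                          min_child_weight = 2,
                                          colsample_bytree = 0.5,
                                          colsample_bylevel = 0.6),
                            seed = seed),
    svm = base_learner_spec("support-vector",
                            params = list(kernel = "polynomial", degree = 2,
                                          cost = 100),
                            seed = seed),
    knn = base_learner_spec("k-nearest-neighbors",
                            params = list(k = 24), seed = seed),
    cart = base_learner_spec("decision-tree", params = list(), seed = seed)
  )
}

#' Fit a base learner on a feature matrix
#'
#' @param spec A [base_learner_spec()].
#' @param x Numeric feature matrix (no missing values).
#' @param y Factor of class labels; its level order fixes the class-column
#'   order of probability output.
#' @return A `base_fit` object usable with [predict_prob()].
#' @export
fit_base_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "base_learner_spec"))
  y <- droplevels(as.factor(y))
  if (anyNA(x)) stop("base learners require imputed data", call. = FALSE)
  x <- as.matrix(x)
  set.seed(spec$seed)
  model <- switch(spec$kind,
    "random-forest" = do.call(randomForest::randomForest,
                              c(list(x = x, y = y), spec$params)),
    "gradient-boosted-trees" = {
      p <- spec$params
      nrounds <- p$nrounds %||% 100
      p$nrounds <- NULL
      params <- c(list(objective = "multi:softprob",
                       num_class = nlevels(y),
                       nthread = 1, verbosity = 0), p)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                     nthread = 1)
      xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                         verbose = 0)
    },
    "support-vector" = do.call(e1071::svm,
                               c(list(x = x, y = y, probability = TRUE),
                                 spec$params)),
    "k-nearest-neighbors" = {
      k <- spec$params$k %||% 5
      caret::knn3(x, y, k = k)
    },
    "decision-tree" = {
      df <- as.data.frame(x)
      df$.y <- y
      do.call(rpart::rpart,
              c(list(formula = .y ~ ., data = df, method = "class"),
                spec$params))
    })
  structure(list(spec = spec, model = model, levels = levels(y),
                 features = colnames(x)),
            class = "base_fit")
}

#' Class-probability predictions from a fitted base learner
#'
#' @param fit A `base_fit` from [fit_base_learner()].
#' @param x Numeric feature matrix with the training columns.
#' @return Numeric matrix `nrow(x)` by `length(fit$levels)`, columns in
#'   the training level order; each row sums to 1.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "base_fit"))
  x <- as.matrix(x)
  if (!is.null(fit$features) && !is.null(colnames(x))) {
    if (!identical(colnames(x), fit$features)) {
      if (!all(fit$features %in% colnames(x))) {
        stop("prediction columns do not match training columns",
             call. = FALSE)
      }
      x <- x[, fit$features, drop = FALSE]
    }
  }
  p <- switch(fit$spec$kind,
    "random-forest" = predict(fit$model, x, type = "prob"),
    "gradient-boosted-trees" = {
      pr <- predict(fit$model, xgboost::xgb.DMatrix(x, nthread = 1))
      m <- if (is.matrix(pr)) pr else
        matrix(pr, ncol = length(fit$levels), byrow = TRUE)
      colnames(m) <- fit$levels
      m
    },
    "support-vector" = {
      pr <- predict(fit$model, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    "k-nearest-neighbors" = predict(fit$model, x, type = "prob"),
    "decision-tree" = predict(fit$model, as.data.frame(x), type = "prob"))
  p <- p[, fit$levels, drop = FALSE]
  p <- p / rowSums(p)
  rownames(p) <- NULL
  unname(p) -> p
  colnames(p) <- fit$levels
  p
}

#' Hard-label predictions from a fitted base learner
#'
#' The argmax of [predict_prob()], ties broken towards the lowest class
#' index (the encoding order).
#'
#' @inheritParams predict_prob
#' @return Factor of predicted labels with the training levels.
#' @export
predict_label <- function(fit, x) {
  p <- predict_prob(fit, x)
  factor(fit$levels[max.col(p, ties.method = "first")], levels = fit$levels)
}
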