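#' Grid for tuning the gate and voting weights
#'
#' The default candidates form a coarse grid containing the operating
#' point reported for the obstetric cohort
#' (`theta = 0.001`, weights `(0.19, 0.01, 0.73)`).
#'
#' @param theta Candidate gate widths in `[0, 1]`.
#' @param weights Either a list with components `c0`, `c1`, `c2` of
#'   candidate weight values in `[0, 1]`, or a single numeric vector used
#'   for all three slots. Triples with zero sum are dropped.
#' @param folds,repeats Cross-validation protocol used inside tuning.
#' @param seed Integer seed.
#' @return A `tune_grid` object.
#' @export
tune_grid <- function(theta = c(0.0005, 0.001, 0.002, 0.005, 0.01, 0.05,
                                0.1),
                      weights = c(0.01, 0.05, 0.1, 0.19, 0.25, 0.5, 0.73,
                                  1.0),
                      folds = 10L, repeats = 3L, seed = 1L) {
  if (!length(theta) || any(theta < 0 | theta > 1)) {
    stop("theta candidates must be a non-empty set within [0, 1]",
         call. = FALSE)
  }
  if (!is.list(weights)) weights <- list(c0 = weights, c1 = weights,
                                         c2 = weights)
  stopifnot(all(c("c0", "c1", "c2") %in% names(weights)))
  for (w in weights) {
    if (!length(w) || any(w < 0 | w > 1)) {
      stop("weight candidates must be non-empty sets within [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(theta = theta, weights = weights,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "tune_grid")
}

#' Tune secondary classifiers, the gate, and the voting weights
#'
#' Jointly searches every unordered pair of secondary classifiers from
#' `pool`, every candidate `theta`, and every weight triple, scoring each
#' configuration by repeated stratified cross-validated accuracy. Base
#' learners are fitted once per fold and their held-out probability
#' blocks cached, so the (pair, theta, weights) sweep costs only argmax
#' arithmetic. Ties are broken by smaller accuracy standard deviation,
#' then lexicographically smaller weights.
#'
#' @param x A labelled `cohort_table` (preprocessed).
#' @param primary A [base_learner_spec()] for the primary classifier.
#' @param pool Named list of at least two candidate
#'   [base_learner_spec()]s for the secondary slots.
#' @param grid A [tune_grid()].
#' @param voting `"soft"` or `"hard"`.
#' @return A `tune_result`: list with `best_config` (an
#'   [ensemble_config()]) and `table` (one row per configuration with
#'   `c1`, `c2`, `theta`, `w_c0`, `w_c1`, `w_c2`, `mean_acc`,
#'   `std_acc`), sorted best-first.
#' @export
tune_wivela <- function(x, primary, pool, grid = tune_grid(),
                        voting = c("soft", "hard")) {
  voting <- match.arg(voting)
  stopifnot(inherits(primary, "base_learner_spec"))
  if (length(pool) < 2) stop("pool needs at least 2 candidates",
                             call. = FALSE)
  if (is.null(names(pool)) || any(!nzchar(names(pool)))) {
    stop("pool must be a named list", call. = FALSE)
  }
  y <- cohort_outcome(x)
  if (is.null(y)) stop("tuning needs a labelled cohort", call. = FALSE)
  lv <- levels(droplevels(y))

  triples <- expand.grid(w_c0 = grid$weights$c0, w_c1 = grid$weights$c1,
                         w_c2 = grid$weights$c2,
                         KEEP.OUT.ATTRS = FALSE)
  triples <- triples[rowSums(triples) > 0, , drop = FALSE]
  if (!nrow(triples)) stop("weight grid is empty after filtering",
                           call. = FALSE)
  pairs <- utils::combn(names(pool), 2, simplify = FALSE)

  # cache held-out probability blocks per fold for primary + pool
  fold_blocks <- list()
  fold_truth <- list()
  for (r in seq_len(grid$repeats)) {
    assignment <- stratified_folds(droplevels(y), grid$folds,
                                   grid$seed + r)
    for (f in seq_len(grid$folds)) {
      test_idx <- which(assignment == f)
      train <- subset_rows(x, -test_idx)
      test_x <- feature_matrix(subset_rows(x, test_idx))
      train_x <- feature_matrix(train)
      train_y <- factor(as.character(cohort_outcome(train)), levels = lv)
      blocks <- lapply(c(list(.primary = primary), pool), function(spec) {
        predict_prob(fit_base_learner(spec, train_x, train_y), test_x)
      })
      fold_blocks[[length(fold_blocks) + 1L]] <- blocks
      fold_truth[[length(fold_truth) + 1L]] <- as.character(y[test_idx])
    }
  }

  score_combo <- function(pair, theta, w) {
    accs <- vapply(seq_along(fold_blocks), function(i) {
      b <- fold_blocks[[i]]
      p0 <- b$.primary
      inherited <- gate_mask(p0, theta)
      pred <- character(nrow(p0))
      if (any(inherited)) {
        pred[inherited] <- lv[max.col(p0[inherited, , drop = FALSE],
                                      ties.method = "first")]
      }
      if (any(!inherited)) {
        vb <- list(p0[!inherited, , drop = FALSE],
                   b[[pair[1]]][!inherited, , drop = FALSE],
                   b[[pair[2]]][!inherited, , drop = FALSE])
        pred[!inherited] <- as.character(
          weighted_vote(vb, w, voting, levels = lv))
      }
      mean(pred == fold_truth[[i]])
    }, double(1))
    c(mean(accs), stats::sd(accs))
  }

  rows <- list()
  for (pair in pairs) {
    for (theta in grid$theta) {
      for (t in seq_len(nrow(triples))) {
        w <- as.double(triples[t, ])
        ms <- score_combo(pair, theta, w)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          c1 = pair[1], c2 = pair[2], theta = theta,
          w_c0 = w[1], w_c1 = w[2], w_c2 = w[3],
          mean_acc = ms[1], std_acc = ms[2])
      }
    }
  }
  tbl <- dplyr::bind_rows(rows)
  tbl <- tbl[order(-tbl$mean_acc, tbl$std_acc,
                   tbl$w_c0, tbl$w_c1, tbl$w_c2), ]
  best <- tbl[1, ]
  best_config <- ensemble_config(
    theta = best$theta,
    weights = c(best$w_c0, best$w_c1, best$w_c2),
    learners = list(c0 = primary, c1 = pool[[best$c1]],
                    c2 = pool[[best$c2]]),
    voting = voting)
  structure(list(best_config = best_config, table = tbl,
                 protocol = grid),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  b <- x$table[1, ]
  cat(sprintf(
    "<tune_result> best: (%s, %s), theta=%g, w=(%g, %g, %g), acc %.4f (sd %.4f)\n",
    b$c1, b$c2, b$theta, b$w_c0, b$w_c1, b$w_c2, b$mean_acc, b$std_acc))
  cat("  configurations evaluated: ", nrow(x$table), "\n", sep = "")
  invisible(x)
}
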