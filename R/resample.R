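#' Resampler configuration
#'
#' @param strategy `"smote"` (oversample every class up to the majority
#'   count), `"smote+undersample"` (move every class to
#'   `target_ratios * n`, oversampling minorities and randomly
#'   undersampling majorities), or `"none"`.
#' @param target_ratios Named numeric vector of desired class proportions
#'   (must sum to 1); used by `"smote+undersample"`. Default: equal shares
#'   over the classes present.
#' @param neighbors Number of same-class nearest neighbours SMOTE
#'   interpolates towards.
#' @param seed Integer seed; resampling is deterministic given the seed.
#' @return A `resampler_config` object.
#' @export
resampler_config <- function(strategy = c("smote+undersample", "smote", "none"),
                             target_ratios = NULL, neighbors = 5L,
                             seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is.null(target_ratios)) {
    if (abs(sum(target_ratios) - 1) > 1e-8) {
      stop("target_ratios must sum to 1", call. = FALSE)
    }
  }
  structure(list(strategy = strategy, target_ratios = target_ratios,
                 neighbors = as.integer(neighbors), seed = as.integer(seed)),
            class = "resampler_config")
}

#' SMOTE oversampling with optional random undersampling
#'
#' Synthetic minority samples are generated the canonical way: pick a
#' minority sample, pick one of its `neighbors` nearest same-class
#' neighbours in (Euclidean) feature space, and draw a new point uniformly
#' on the segment between the two — i.e. every synthetic row is a convex
#' combination of two same-class source rows. Majority classes are
#' undersampled by random draws without replacement. Apply this to
#' training rows only: resampling before a train/test split leaks
#' synthetic copies of test-neighbourhood structure into training.
#'
#' @param x A labelled `cohort_table` with no missing values.
#' @param cfg A [resampler_config()].
#' @return A resampled `cohort_table`. Rows of classes that are not
#'   undersampled keep their original values (originals precede synthetic
#'   rows of each oversampled class).
#' @export
resample_cohort <- function(x, cfg = resampler_config()) {
  if (cfg$strategy == "none") return(x)
  if (is.null(x$outcome)) stop("resampling needs a labelled cohort",
                               call. = FALSE)
  if (anyNA(x$data)) stop("resampling needs imputed data", call. = FALSE)

  y <- x$outcome
  counts <- table(y)
  classes <- names(counts)
  n <- length(y)

  targets <- switch(cfg$strategy,
    "smote" = stats::setNames(rep(max(counts), length(classes)), classes),
    "smote+undersample" = {
      ratios <- cfg$target_ratios %||%
        stats::setNames(rep(1 / length(classes), length(classes)), classes)
      absent <- setdiff(classes, names(ratios))
      if (length(absent)) {
        stop("target_ratios missing class(es): ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
      stats::setNames(round(unname(ratios[classes]) * n), classes)
    })

  for (cl in classes) {
    if (targets[[cl]] > counts[[cl]] &&
        counts[[cl]] < cfg$neighbors + 1L) {
      stop("class '", cl, "' has ", counts[[cl]],
           " samples, fewer than neighbors + 1 = ", cfg$neighbors + 1L,
           "; reduce `neighbors`", call. = FALSE)
    }
  }

  X <- feature_matrix(x)
  set.seed(cfg$seed)
  pieces_idx <- list()
  pieces_syn <- list()
  for (cl in classes) {
    idx <- which(y == cl)
    tgt <- targets[[cl]]
    if (tgt <= length(idx)) {
      keep <- if (tgt == length(idx)) idx else sort(sample(idx, tgt))
      pieces_idx[[cl]] <- keep
    } else {
      pieces_idx[[cl]] <- idx
      n_syn <- tgt - length(idx)
      Xc <- X[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      k <- min(cfg$neighbors, length(idx) - 1L)
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      base_pick <- sample(length(idx), n_syn, replace = TRUE)
      nb_pick <- vapply(base_pick,
                        function(i) nn[i, sample.int(k, 1L)], integer(1))
      lambda <- stats::runif(n_syn)
      syn <- Xc[base_pick, , drop = FALSE] +
        lambda * (Xc[nb_pick, , drop = FALSE] - Xc[base_pick, , drop = FALSE])
      pieces_syn[[cl]] <- syn
    }
  }

  keep_idx <- unlist(pieces_idx, use.names = FALSE)
  data_out <- x$data[keep_idx, , drop = FALSE]
  y_out <- as.character(y[keep_idx])
  for (cl in names(pieces_syn)) {
    syn_df <- tibble::as_tibble(as.data.frame(pieces_syn[[cl]]))
    names(syn_df) <- names(x$data)
    data_out <- dplyr::bind_rows(data_out, syn_df)
    y_out <- c(y_out, rep(cl, nrow(syn_df)))
  }
  cohort_table(data_out, x$schema, outcome = y_out, enc = x$enc)
}
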