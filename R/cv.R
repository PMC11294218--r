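#' Cross-validation split generators
#'
#' `kfold_splits` partitions samples into k folds of near-equal size
#' (sizes differ by at most 1), stratified by label so each fold keeps
#' the overall class distribution; classes with fewer than k samples
#' trigger a fall-back to unstratified folds with a warning.  Splitting
#' is at the segment level: segments of one trial may share a fold (this
#' mirrors the within-subject protocol and inflates accuracy relative
#' to) `leave_one_trial_out`, which holds out all segments of one trial
#' per split, and `leave_one_subject_out`, which holds out all samples
#' of one subject.
#'
#' @param labels per-sample labels (used for stratification).
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return list of `list(train, test)` index pairs; test sets are
#'   pairwise disjoint and their union is all samples.
#' @export
kfold_splits <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  stopifnot(n >= k, k >= 2L)
  set.seed(seed)
  fold <- integer(n)
  counts <- table(labels)
  if (any(counts < k)) {
    warning("class with fewer than k samples; using unstratified folds",
            call. = FALSE)
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  } else {
    for (ix in split(seq_len(n), labels)) {
      ix <- sample(ix)
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' @rdname kfold_splits
#' @param sample_index data.frame with a `trial` column (and optionally
#'   `subject`; trials are then nested within subjects), as produced by
#'   [extract_features()].
#' @export
leave_one_trial_out <- function(sample_index) {
  key <- if ("subject" %in% names(sample_index))
    paste(sample_index$subject, sample_index$trial, sep = "/")
  else as.character(sample_index$trial)
  ids <- unique(key)
  if (length(ids) < 2L)
    stop("leave-one-trial-out needs at least 2 trials", call. = FALSE)
  lapply(ids, function(id) {
    test <- which(key == id)
    list(train = setdiff(seq_along(key), test), test = test)
  })
}

#' @rdname kfold_splits
#' @param subjects per-sample subject identifiers.
#' @export
leave_one_subject_out <- function(subjects) {
  ids <- unique(subjects)
  if (length(ids) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  lapply(ids, function(id) {
    test <- which(subjects == id)
    list(train = which(subjects != id), test = test)
  })
}

#' Confusion matrix
#'
#' @param preds,labels 0-based integer vectors of equal, nonzero length.
#' @param num_classes number of classes (default: inferred).
#' @return list with `counts` (rows = true class) and `percent`
#'   (row-normalized, rows sum to 100 for non-empty classes).
#' @export
confusion_matrix <- function(preds, labels, num_classes = NULL) {
  stopifnot(length(preds) == length(labels), length(preds) > 0L)
  k <- num_classes %||% (max(c(preds, labels)) + 1L)
  m <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1),
                                        predicted = 0:(k - 1)))
  for (i in seq_along(preds))
    m[labels[i] + 1L, preds[i] + 1L] <- m[labels[i] + 1L, preds[i] + 1L] + 1L
  rs <- rowSums(m)
  pct <- 100 * m / ifelse(rs == 0, 1, rs)
  list(counts = m, percent = pct)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` -- the fraction of correctly
#' predicted samples (the binary formula generalizes to the multiclass
#' trace of the confusion matrix).
#'
#' @inheritParams confusion_matrix
#' @export
accuracy <- function(preds, labels) {
  stopifnot(length(preds) == length(labels), length(preds) > 0L)
  mean(preds == labels)
}

#' Train and evaluate across cross-validation splits
#'
#' For every split: asserts train/test disjointness, trains a fresh model
#' on the training indices (early-stopping validation is carved out of
#' the training split only), and evaluates on the held-out test set.
#' Per-fold seeds are derived from `config$seed` so the whole run is
#' reproducible.
#'
#' @inheritParams train_damgcn
#' @param splits list of `list(train, test)` pairs from one of the split
#'   generators.
#' @param protocol tag stored in the result (e.g. `"kfold"`, `"loto"`,
#'   `"loso"`).
#' @param keep_fits keep the per-fold `damgcn_fit` objects (memory-heavy).
#' @return a `damgcn_eval`: `fold_accuracy`, `mean_accuracy`,
#'   `sd_accuracy`, pooled `confusion` (counts + percent), `protocol`,
#'   and optionally `fits`.
#' @export
cv_evaluate <- function(features, labels, splits, graph = NULL,
                        model_config, config = train_config(),
                        protocol = "kfold", keep_fits = FALSE,
                        verbose = FALSE) {
  labels <- as.integer(labels)
  accs <- numeric(length(splits))
  preds_all <- integer(0)
  labs_all <- integer(0)
  fits <- if (keep_fits) vector("list", length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    if (length(intersect(sp$train, sp$test)) > 0L)
      stop("train/test leakage in split ", f, call. = FALSE)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    fit <- train_damgcn(features, labels, graph, model_config, fold_cfg,
                        train_idx = sp$train, verbose = verbose)
    pr <- damgcn_predict(fit$model, features[sp$test, , , drop = FALSE])
    accs[f] <- accuracy(pr, labels[sp$test])
    preds_all <- c(preds_all, pr)
    labs_all <- c(labs_all, labels[sp$test])
    if (keep_fits) fits[[f]] <- fit
    if (verbose)
      message(sprintf("[%s] fold %d/%d accuracy %.3f", protocol, f,
                      length(splits), accs[f]))
  }
  structure(list(fold_accuracy = accs, mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs),
                 confusion = confusion_matrix(
                   preds_all, labs_all,
                   num_classes = model_config$num_classes),
                 protocol = protocol, fits = fits),
            class = "damgcn_eval")
}

#' @export
print.damgcn_eval <- function(x, ...) {
  cat("<damgcn_eval> ", x$protocol, ": mean accuracy ",
      sprintf("%.2f%%", 100 * x$mean_accuracy), " (sd ",
      sprintf("%.2f", 100 * x$sd_accuracy), ") over ",
      length(x$fold_accuracy), " folds\n", sep = "")
  invisible(x)
}
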