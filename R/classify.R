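#' Pinned gradient-boosted-tree training configuration
#'
#' The classifier is a multiclass gradient-boosted tree ensemble. "Library
#' defaults" drift across versions, so the effective configuration is
#' pinned here as a recorded snapshot: 100 boosting rounds, learning rate
#' 0.3, maximum depth 6, no subsampling, softmax objective, single thread
#' (single-threaded training makes results bit-reproducible across runs and
#' platforms).
#'
#' @return Named list of hyperparameters.
#' @export
classifier_defaults <- function() {
  list(
    nrounds = 100,
    eta = 0.3,
    max_depth = 6,
    gamma = 0,
    min_child_weight = 1,
    subsample = 1,
    colsample_bytree = 1,
    nthread = 1
  )
}

as_feature_matrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop_validation("feature matrix contains missing or non-finite values")
  }
  m
}

#' Train the four-class epoch classifier
#'
#' Fits a multiclass gradient-boosted tree ensemble (softmax objective) on
#' a feature matrix of dB-normalized sub-band powers plus the theta/alpha
#' ratio. Training is deterministic given `seed` (single-threaded,
#' seeded).
#'
#' @param features Numeric matrix or data.frame, one row per epoch, with
#'   the 7 spectral features.
#' @param labels Character vector of class labels, one per row; at least
#'   two distinct classes and at least 10 rows.
#' @param seed Integer seed for the tree builder.
#' @param params Hyperparameters; defaults to [classifier_defaults()].
#' @param levels Class encoding; fixed alphabetical order by default so
#'   confusion matrices are comparable across runs.
#' @return Object of class `eeg_classifier`: the fitted booster plus the
#'   feature schema, class encoding, training config and seed.
#' @export
train_classifier <- function(features, labels, seed = 1L,
                             params = classifier_defaults(),
                             levels = sort(unique(as.character(labels)))) {
  m <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(m) != length(labels)) {
    stop_validation("one label per feature row required")
  }
  if (nrow(m) < 10L) stop_validation("need at least 10 training rows")
  if (length(unique(labels)) < 2L) {
    stop_validation("training labels contain a single class")
  }
  if (!all(labels %in% levels)) {
    stop_validation("labels outside the declared class encoding")
  }
  y <- match(labels, levels) - 1L
  dtrain <- xgboost::xgb.DMatrix(m, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "multi:softmax",
      num_class = length(levels),
      eta = params$eta,
      max_depth = params$max_depth,
      gamma = params$gamma,
      min_child_weight = params$min_child_weight,
      subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      nthread = params$nthread,
      seed = as.integer(seed)
    ),
    data = dtrain,
    nrounds = params$nrounds,
    verbose = 0
  )
  structure(
    list(
      booster = booster,
      feature_names = colnames(m),
      levels = levels,
      params = params,
      seed = as.integer(seed)
    ),
    class = "eeg_classifier"
  )
}

#' @export
print.eeg_classifier <- function(x, ...) {
  cat(sprintf(
    "<eeg_classifier> %d-class gradient-boosted trees (%d rounds, depth %d, eta %g)\nclasses: %s\n",
    length(x$levels), x$params$nrounds, x$params$max_depth, x$params$eta,
    paste(x$levels, collapse = ", ")
  ))
  invisible(x)
}

#' Predict epoch class labels
#'
#' @param object A trained `eeg_classifier`.
#' @param features Feature matrix with the same columns (names and order)
#'   as at training time. Zero rows give a zero-length result.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.eeg_classifier <- function(object, features, ...) {
  m <- as_feature_matrix(features)
  if (nrow(m) == 0L) return(character(0))
  if (!identical(colnames(m), object$feature_names)) {
    stop_validation(sprintf(
      "feature schema mismatch: expected [%s], got [%s]",
      paste(object$feature_names, collapse = ", "),
      paste(colnames(m), collapse = ", ")
    ))
  }
  idx <- stats::predict(object$booster, xgboost::xgb.DMatrix(m, nthread = 1))
  object$levels[as.integer(idx) + 1L]
}

#' Save / load a trained classifier
#'
#' The booster is serialized to its library-native raw format and bundled
#' with the feature schema and class encoding; a reloaded model yields
#' bit-identical predictions.
#'
#' @param model An `eeg_classifier`.
#' @param path File path.
#' @return `path` invisibly for save; the model for load.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "eeg_classifier"))
  payload <- model
  payload$booster <- xgboost::xgb.save.raw(model$booster)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("model file not found: %s", path))
  payload <- readRDS(path)
  payload$booster <- xgboost::xgb.load.raw(payload$booster)
  structure(payload, class = "eeg_classifier")
}

#' Classification metrics: accuracy, per-class precision and recall
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) over
#' the given class encoding and derives overall accuracy (trace / total),
#' per-class precision TP/(TP+FP) and recall TP/(TP+FN). A class never
#' predicted (or never present) would divide by zero; its precision
#' (resp. recall) is reported as 0 and the class is listed in
#' `zero_division`.
#'
#' @param truth,predicted Equal-length character vectors of class labels.
#' @param levels Class encoding; defaults to the sorted union of observed
#'   labels.
#' @return Object of class `classification_report`: list with `accuracy`,
#'   `precision`, `recall` (named per class), `confusion` (square count
#'   matrix), `support`, and `zero_division` (character vector of flagged
#'   classes).
#' @examples
#' classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
classification_metrics <- function(truth, predicted,
                                   levels = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted must have equal length")
  }
  bad <- setdiff(c(truth, predicted), levels)
  if (length(bad)) {
    stop_validation(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  cm <- table(
    factor(truth, levels = levels),
    factor(predicted, levels = levels)
  )
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  flagged <- levels[pred_tot == 0 | true_tot == 0]
  structure(
    list(
      accuracy = sum(tp) / sum(cm),
      precision = stats::setNames(as.numeric(precision), levels),
      recall = stats::setNames(as.numeric(recall), levels),
      confusion = cm,
      support = stats::setNames(as.numeric(true_tot), levels),
      zero_division = flagged
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.4f over %d epochs\n",
              x$accuracy, sum(x$confusion)))
  tab <- data.frame(
    precision = round(x$precision, 4),
    recall = round(x$recall, 4),
    support = x$support
  )
  print(tab)
  if (length(x$zero_division)) {
    cat("zero-division classes:", paste(x$zero_division, collapse = ", "), "\n")
  }
  invisible(x)
}

#' k-fold cross-validation with fold-aware baseline normalization
#'
#' Implements the validation protocol for the epoch classifier: pooled
#' epochs from all subjects are split into `k` folds by seeded random
#' sampling (epoch-level, not subject-level). Within each fold the decibel
#' baseline is recomputed from the training fold only — for every subject,
#' the first `n_first` of its epochs that fall in the training fold — so no
#' test-epoch power leaks into the feature normalization. Per-fold
#' accuracy, precision and recall are reported together with their means
#' and the pooled confusion matrix.
#'
#' An optional subject-grouped split (`group_by_subject = TRUE`) holds out
#' whole subjects per fold instead, the stricter protocol for generality
#' claims.
#'
#' @param epochs List of `eeg_epoch` objects.
#' @param labels Character vector of class labels, one per epoch.
#' @param subjects Subject id per epoch (`NULL` = single subject).
#' @param k Number of folds (default 10); every class needs at least `k`
#'   members.
#' @param seed Integer seed controlling the fold split and tree builder.
#' @param scheme,segment_s,overlap Spectral parameters, see [welch_psd()].
#' @param n_first Epochs per subject entering the baseline (default 5).
#' @param params Classifier hyperparameters.
#' @param group_by_subject Use subject-grouped folds instead of pooled
#'   epoch-level folds.
#' @param powers Optional precomputed [band_power_matrix()] for `epochs`.
#' @return Object of class `cv_report`: list with `mean_accuracy`,
#'   `mean_precision`, `mean_recall`, `fold_accuracy`, `folds` (per-fold
#'   `classification_report`s), `confusion` (pooled), `k`, `seed`.
#' @export
cross_validate <- function(epochs, labels, subjects = NULL, k = 10, seed = 1L,
                           scheme = sub_band_scheme(), segment_s = 4,
                           overlap = 0.5, n_first = 5,
                           params = classifier_defaults(),
                           group_by_subject = FALSE, powers = NULL) {
  n <- length(epochs)
  labels <- as.character(labels)
  if (length(labels) != n) stop_validation("one label per epoch required")
  if (is.null(subjects)) subjects <- rep("S1", n)
  counts <- table(labels)
  if (any(counts < k)) {
    stop_validation(sprintf(
      "class(es) with fewer than k = %d members: %s",
      k, paste(names(counts)[counts < k], collapse = ", ")
    ))
  }
  levels <- sort(unique(labels))
  if (is.null(powers)) {
    powers <- band_power_matrix(epochs, scheme, segment_s, overlap)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (group_by_subject) {
    subj <- unique(subjects)
    if (length(subj) < k) {
      stop_validation("fewer subjects than folds for a subject-grouped split")
    }
    subj_fold <- stats::setNames(
      rep_len(seq_len(k), length(subj))[sample.int(length(subj))], subj
    )
    fold <- subj_fold[subjects]
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }

  reports <- vector("list", k)
  pooled <- NULL
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    train_subj <- subjects[train]
    # per-subject leading epochs within the training fold
    keep <- unlist(lapply(unique(train_subj), function(s) {
      pos <- train[train_subj == s]
      pos[seq_len(min(n_first, length(pos)))]
    }))
    base <- colMeans(powers[keep, , drop = FALSE])
    if (any(base <= 0)) stop_validation("zero baseline power in a fold")
    baseline <- structure(
      list(powers = base, n_epochs_used = length(keep),
           provenance = data.frame(subject = subjects[keep],
                                   epoch_position = keep)),
      class = "baseline_powers"
    )
    feats <- features_from_powers(powers, baseline)
    model <- train_classifier(feats[train, , drop = FALSE], labels[train],
                              seed = seed, params = params, levels = levels)
    pred <- predict(model, feats[test, , drop = FALSE])
    rep_f <- classification_metrics(labels[test], pred, levels = levels)
    reports[[f]] <- rep_f
    pooled <- if (is.null(pooled)) rep_f$confusion else pooled + rep_f$confusion
  }

  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  prec <- rowMeans(vapply(reports, function(r) r$precision,
                          numeric(length(levels))))
  rec <- rowMeans(vapply(reports, function(r) r$recall,
                         numeric(length(levels))))
  structure(
    list(
      mean_accuracy = mean(acc),
      mean_precision = stats::setNames(prec, levels),
      mean_recall = stats::setNames(rec, levels),
      fold_accuracy = acc,
      folds = reports,
      confusion = pooled,
      k = k,
      seed = as.integer(seed)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV: mean accuracy %.4f (folds %s)\n",
              x$k, x$mean_accuracy,
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  tab <- data.frame(
    mean_precision = round(x$mean_precision, 4),
    mean_recall = round(x$mean_recall, 4)
  )
  print(tab)
  invisible(x)
}
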