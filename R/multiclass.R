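#' Multiclass evaluation: confusion matrix and macro-F1
#'
#' @param predicted,truth Class label vectors of equal length.
#' @param classes Optional class set (default: union of both, sorted).
#' @return An object of class `multiclass_result`: `confusion` (rows =
#'   true, columns = predicted), `per_class_f1` (0 when precision and
#'   recall are both 0), `macro_f1`.
#' @export
evaluate_multiclass <- function(predicted, truth, classes = NULL) {
  stop_if_not(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  stop_if_not(length(truth) > 0, "empty input")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(union(predicted, truth))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  f1 <- vapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[, k])
    rec_den <- sum(cm[k, ])
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 0)
  names(f1) <- classes
  structure(list(confusion = cm, per_class_f1 = f1,
                 macro_f1 = mean(f1)),
            class = "multiclass_result")
}

#' @export
print.multiclass_result <- function(x, ...) {
  cat(sprintf("<multiclass_result> macro-F1 %.3f over %d classes\n",
              x$macro_f1, length(x$per_class_f1)))
  print(round(x$per_class_f1, 3))
  invisible(x)
}

#' Stratified k-fold cross-validated CNN evaluation
#'
#' Splits the events into `k` stratified folds; each fold is held out in
#' turn, doubling as the early-stopping validation set, and the per-fold
#' macro-F1 is recorded. The reported confusion matrix is the one from
#' the fold with the best macro-F1.
#'
#' @param events An [isgc_events()] table.
#' @param config A [cnn_config()].
#' @param k Number of folds (every class must have at least `k` members).
#' @param labels Class labels (default: the table's `true_class`).
#' @return A `crossfold_result`: `fold_f1`, `mean_f1`, `sd_f1`,
#'   `best_fold`, `best_confusion`, `per_class_f1` (best fold).
#' @export
crossfold_eval <- function(events, config, k = 10L,
                           labels = events$info$true_class) {
  labels <- as.character(labels)
  folds <- stratified_folds(labels, k, seed = config$seed)
  classes <- sort(unique(labels))
  fold_f1 <- numeric(k)
  results <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    cfg <- config
    cfg$seed <- event_seed(config$seed, 37L * f)
    model <- train_cnn(events[tr], events[!tr], cfg,
                       train_labels = labels[tr],
                       val_labels = labels[!tr])
    pred <- predict_cnn(model, events[!tr])
    res <- evaluate_multiclass(pred$labels, labels[!tr], classes)
    fold_f1[f] <- res$macro_f1
    results[[f]] <- res
  }
  best <- which.max(fold_f1)
  structure(list(fold_f1 = fold_f1, mean_f1 = mean(fold_f1),
                 sd_f1 = stats::sd(fold_f1), best_fold = best,
                 best_confusion = results[[best]]$confusion,
                 per_class_f1 = results[[best]]$per_class_f1),
            class = "crossfold_result")
}

#' @export
print.crossfold_result <- function(x, ...) {
  cat(sprintf("<crossfold_result> macro-F1 %.3f +/- %.3f over %d folds (best fold %d)\n",
              x$mean_f1, x$sd_f1, length(x$fold_f1), x$best_fold))
  invisible(x)
}

#' Intra- versus inter-batch transfer evaluation
#'
#' Intra: a stratified 70/30 train/test split within batch A (10% of the
#' training part carved out for early stopping). Inter: train on all of
#' batch A, test on all of batch B. The gap between the two macro-F1
#' values measures how much batch (donor) variation degrades transfer.
#'
#' @param events_a,events_b [isgc_events()] tables (both must contain all
#'   classes).
#' @param config A [cnn_config()].
#' @return List with `intra` and `inter` macro-F1 values and the two
#'   `multiclass_result`s.
#' @export
transfer_eval <- function(events_a, events_b, config) {
  la <- as.character(events_a$info$true_class)
  lb <- as.character(events_b$info$true_class)
  classes <- sort(unique(la))
  stop_if_not(setequal(classes, unique(lb)),
              "both batches must contain the same classes")

  train_with_carveout <- function(events, labels, seed) {
    carve <- fraction_split(labels, 0.9, seed = seed)
    cfg <- config
    cfg$seed <- seed
    train_cnn(events[carve$train], events[carve$test], cfg,
              train_labels = labels[carve$train],
              val_labels = labels[carve$test])
  }

  sp <- fraction_split(la, 0.7, seed = config$seed)
  m_intra <- train_with_carveout(events_a[sp$train], la[sp$train],
                                 event_seed(config$seed, 11L))
  pred_intra <- predict_cnn(m_intra, events_a[sp$test])
  res_intra <- evaluate_multiclass(pred_intra$labels, la[sp$test], classes)

  m_inter <- train_with_carveout(events_a, la, event_seed(config$seed, 13L))
  pred_inter <- predict_cnn(m_inter, events_b)
  res_inter <- evaluate_multiclass(pred_inter$labels, lb, classes)

  list(intra = res_intra$macro_f1, inter = res_inter$macro_f1,
       intra_result = res_intra, inter_result = res_inter)
}
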