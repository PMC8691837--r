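#' SVM pipeline configuration
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_grid Regularization grid for the grid search.
#' @param gamma_grid Kernel-coefficient grid (rbf only).
#' @param inner_folds Inner stratified folds for hyperparameter selection
#'   (>= 2); selection maximizes inner-CV AUC, ties broken toward smaller
#'   C then smaller gamma.
#' @param modality_set Character vector of waveform modalities and/or
#'   scalar feature names fed to the classifier, in order.
#' @param n_trials Number of random-sampling trials for
#'   [repeated_eval()].
#' @param seed Integer seed.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"),
                       C_grid = 10^(-2:3),
                       gamma_grid = 10^seq(-4, 1),
                       inner_folds = 5L,
                       modality_set = c("dGMI", "ssGMI"),
                       n_trials = 10L, seed = 1L) {
  kernel <- match.arg(kernel)
  stop_if_not(length(C_grid) > 0 && all(C_grid > 0),
              "C_grid must be positive")
  stop_if_not(length(gamma_grid) > 0 && all(gamma_grid > 0),
              "gamma_grid must be positive")
  stop_if_not(is_count(inner_folds) && inner_folds >= 2,
              "inner_folds must be >= 2")
  structure(list(kernel = kernel, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid),
                 inner_folds = as.integer(inner_folds),
                 modality_set = modality_set,
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "svm_config")
}

scalar_feature_names <- function() {
  c("fsc_height", "fsc_width", "fsc_area", "ssc", "bsc")
}

#' Assemble the classifier feature matrix
#'
#' Concatenates the selected waveform segments and scalar features in the
#' declared order, optionally standardizing per feature with a normalizer
#' fitted on training data only.
#'
#' @param events An [isgc_events()] table.
#' @param modality_set Names of waveform modalities and/or scalar or
#'   fluorescence features, in concatenation order.
#' @param normalizer Optional result of [fit_normalizer()].
#' @return Numeric matrix, one row per event.
#' @export
featurize <- function(events, modality_set, normalizer = NULL) {
  blocks <- lapply(modality_set, function(m) {
    if (m %in% names(events$waveforms)) {
      events$waveforms[[m]]
    } else {
      matrix(get_feature(events, m), ncol = 1)
    }
  })
  x <- do.call(cbind, blocks)
  if (!is.null(normalizer)) {
    stop_if_not(ncol(x) == length(normalizer$center),
                "feature dimension does not match normalizer")
    x <- sweep(sweep(x, 2, normalizer$center), 2, normalizer$scale, `/`)
  }
  x
}

#' Fit a per-feature standardizer
#'
#' @param x Feature matrix (training data only).
#' @return List with `center` (means) and `scale` (standard deviations;
#'   constant features get scale 1).
#' @export
fit_normalizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

# Deterministic stratified fold assignment (1..k per row).
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class '", cl, "' has fewer members (", length(idx),
             ") than folds (", k, ")", call. = FALSE)
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

fit_svm_raw <- function(x, y, kernel, cost, gamma) {
  if (kernel == "linear") {
    e1071::svm(x, y, type = "C-classification", kernel = "linear",
               cost = cost, scale = FALSE)
  } else {
    e1071::svm(x, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  }
}

decision_scores <- function(fit, x, flip) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  as.numeric(dv[, 1]) * flip
}

#' Train a grid-searched SVM on labeled events
#'
#' Standardizes features with a normalizer fitted on the training events
#' only, selects the regularization (and, for the rbf kernel, the kernel
#' coefficient) by inner stratified k-fold cross-validated AUC, then
#' refits on all training data with the chosen hyperparameters.
#'
#' @param events Training [isgc_events()].
#' @param labels Binary labels, one per event.
#' @param config An [svm_config()].
#' @param positive The positive-class label value; defaults to the larger
#'   of the two sorted unique labels.
#' @return An object of class `svm_model` with the fitted classifier, the
#'   chosen hyperparameters, the per-combination inner-CV AUC table and
#'   the training normalizer.
#' @export
train_svm <- function(events, labels, config = svm_config(),
                      positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  stop_if_not(length(classes) == 2,
              "training labels must contain exactly two classes")
  if (is.null(positive)) positive <- classes[2]
  x_raw <- featurize(events, config$modality_set)
  normalizer <- fit_normalizer(x_raw)
  x <- featurize(events, config$modality_set, normalizer)
  y <- factor(labels, levels = classes)

  grid <- if (config$kernel == "linear") {
    data.frame(cost = config$C_grid, gamma = NA_real_)
  } else {
    expand.grid(gamma = config$gamma_grid, cost = config$C_grid)
  }
  folds <- stratified_folds(labels, config$inner_folds, config$seed)
  grid$cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(config$inner_folds), function(f) {
      tr <- folds != f
      fit <- fit_svm_raw(x[tr, , drop = FALSE], y[tr], config$kernel,
                         grid$cost[g], grid$gamma[g])
      sc_tr <- decision_scores(fit, x[tr, , drop = FALSE], 1)
      flip_f <- if (mean(sc_tr[labels[tr] == positive]) >=
                      mean(sc_tr[labels[tr] != positive])) 1 else -1
      sc <- decision_scores(fit, x[!tr, , drop = FALSE], flip_f)
      roc_auc(sc, labels[!tr], positive)$auc
    }, 0)
    mean(aucs)
  }, 0)
  # ties toward smaller C then smaller gamma: order grid accordingly
  ord <- order(grid$cost, grid$gamma, na.last = TRUE)
  grid_o <- grid[ord, ]
  best <- grid_o[which.max(grid_o$cv_auc), ]

  fit <- fit_svm_raw(x, y, config$kernel, best$cost, best$gamma)
  sc <- decision_scores(fit, x, 1)
  flip <- if (mean(sc[labels == positive]) >= mean(sc[labels != positive]))
    1 else -1
  structure(list(fit = fit, kernel = config$kernel, cost = best$cost,
                 gamma = best$gamma, cv_auc = best$cv_auc,
                 grid = grid, flip = flip, positive = positive,
                 normalizer = normalizer,
                 modality_set = config$modality_set),
            class = "svm_model")
}

#' Signed SVM decision scores
#'
#' @param model A [train_svm()] model.
#' @param events Events to score.
#' @return Numeric scores; higher means more likely the positive class.
#' @export
svm_score <- function(model, events) {
  stop_if_not(inherits(model, "svm_model"), "model must be an svm_model")
  x <- featurize(events, model$modality_set, model$normalizer)
  decision_scores(model$fit, x, model$flip)
}

#' Export the deployable linear decision function
#'
#' For a linear-kernel model, returns the weight vector and bias in raw
#' feature space (the training normalizer folded in) so that
#' `x %*% w + b` reproduces [svm_score()] exactly — the form a real-time
#' scorer would ship.
#'
#' @param model A linear-kernel [train_svm()] model.
#' @return List with `weights` and `bias`.
#' @export
export_linear_scorer <- function(model) {
  stop_if_not(inherits(model, "svm_model"), "model must be an svm_model")
  if (model$kernel != "linear") {
    stop("only linear-kernel models export a weight vector", call. = FALSE)
  }
  w_std <- as.numeric(t(model$fit$coefs) %*% model$fit$SV) * model$flip
  b_std <- -model$fit$rho * model$flip
  w <- w_std / model$normalizer$scale
  b <- b_std - sum(w_std * model$normalizer$center / model$normalizer$scale)
  list(weights = w, bias = b)
}

#' Repeated random-sampling evaluation
#'
#' Runs `config$n_trials` independent balanced train/test samplings, each
#' training a grid-searched SVM and scoring its held-out events. Reports
#' the per-trial AUCs with their mean and standard deviation, and -
#' separately, since the two summaries differ slightly - the AUC of the
#' vertically averaged mean ROC curve.
#'
#' @param events An [isgc_events()] table.
#' @param labels Binary labels.
#' @param config An [svm_config()].
#' @param n_train_per_class,n_test_per_class Balanced split sizes.
#' @param positive Positive-class label value.
#' @return An object of class `eval_result`: `aucs`, `mean_auc`,
#'   `sd_auc`, `mean_roc`, `auc_mean_roc`, `rocs`, and the last trial's
#'   model.
#' @export
repeated_eval <- function(events, labels, config = svm_config(),
                          n_train_per_class = 300L,
                          n_test_per_class = 300L, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(positive)) positive <- classes[2]
  aucs <- numeric(config$n_trials)
  rocs <- vector("list", config$n_trials)
  model <- NULL
  for (trial in seq_len(config$n_trials)) {
    sp <- balanced_split(labels, n_train_per_class, n_test_per_class,
                         seed = event_seed(config$seed, 1009L * trial))
    trial_cfg <- config
    trial_cfg$seed <- event_seed(config$seed, 1013L * trial)
    model <- train_svm(events[sp$train], labels[sp$train], trial_cfg,
                       positive = positive)
    sc <- svm_score(model, events[sp$test])
    r <- roc_auc(sc, labels[sp$test], positive)
    aucs[trial] <- r$auc
    rocs[[trial]] <- r$roc
  }
  mroc <- mean_roc(rocs)
  auc_mroc <- sum(diff(mroc$fpr) *
                    (utils::head(mroc$tpr, -1) + utils::tail(mroc$tpr, -1)) / 2)
  structure(list(aucs = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs), rocs = rocs, mean_roc = mroc,
                 auc_mean_roc = auc_mroc, model = model,
                 positive = positive),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d trials: AUC %.3f +/- %.3f (mean ROC AUC %.3f)\n",
              length(x$aucs), x$mean_auc, x$sd_auc, x$auc_mean_roc))
  invisible(x)
}

#' Simulate an in-silico sort
#'
#' Keeps the events whose score exceeds the threshold (the real-time sort
#' decision) and reports enrichment: pre-sort target fraction, post-sort
#' purity, and yield.
#'
#' @param events Scored events.
#' @param model An [svm_model] (or `NULL` if `scores` given).
#' @param threshold Sort threshold on the decision score (default 0, the
#'   decision boundary).
#' @param target_class Class being enriched.
#' @param labels True labels (default: the event table's `true_class`).
#' @param scores Optional precomputed scores (bypasses the model).
#' @return An object of class `sort_report`: `pre_fraction`, `purity`
#'   (`NA` if nothing is kept), `yield`, `n_kept`, `threshold`.
#' @export
simulate_sort <- function(events, model = NULL, threshold = 0,
                          target_class, labels = NULL, scores = NULL) {
  if (is.null(labels)) labels <- events$info$true_class
  if (is.null(scores)) {
    stop_if_not(!is.null(model), "either model or scores must be given")
    scores <- svm_score(model, events)
  }
  is_target <- labels == target_class
  kept <- scores > threshold
  purity <- if (any(kept)) mean(is_target[kept]) else NA_real_
  yield <- if (any(is_target)) sum(kept & is_target) / sum(is_target) else
    NA_real_
  structure(list(pre_fraction = mean(is_target), purity = purity,
                 yield = yield, n_kept = sum(kept), threshold = threshold),
            class = "sort_report")
}

#' @export
print.sort_report <- function(x, ...) {
  cat(sprintf("<sort_report> purity %.1f%% (pre-sort %.1f%%), yield %.1f%%, %d kept\n",
              100 * x$purity, 100 * x$pre_fraction, 100 * x$yield,
              x$n_kept))
  invisible(x)
}

#' Ideal throughput from the acquisition time
#'
#' Assuming cells evenly spaced by one structured-illumination length so
#' waveforms are acquired back to back, throughput is the inverse of the
#' per-cell acquisition time: 100 microseconds per cell gives 10,000
#' cells per second.
#'
#' @param acquisition_time_per_cell Acquisition time per cell in seconds
#'   (> 0).
#' @return Events per second.
#' @export
estimate_throughput <- function(acquisition_time_per_cell) {
  stop_if_not(is_number(acquisition_time_per_cell) &&
                acquisition_time_per_cell > 0,
              "acquisition time must be > 0")
  1 / acquisition_time_per_cell
}
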