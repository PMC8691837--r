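#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values, giving an
#' ROC from (0, 0) to (1, 1); the area is computed by the trapezoid rule,
#' which equals the Mann-Whitney probability that a random positive
#' outscores a random negative with ties counted one half.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels Binary labels (logical, or values matching `positive`).
#' @param positive The positive-class label value (default `TRUE`).
#' @return List with `roc` (data frame of `fpr`, `tpr`, nondecreasing in
#'   both coordinates) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = TRUE) {
  y <- labels == positive
  n_pos <- sum(y)
  n_neg <- sum(!y)
  stop_if_not(n_pos > 0 && n_neg > 0,
              "both classes must be present to compute a ROC")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # collapse tied scores so each distinct threshold is one ROC point
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Vertically averaged mean ROC curve
#'
#' Interpolates each curve's TPR at a fixed FPR grid (linear
#' interpolation, upper envelope at vertical segments) and averages
#' across curves.
#'
#' @param rocs List of ROC data frames (`fpr`, `tpr`).
#' @param fpr_grid FPR grid; default 101 uniform points.
#' @return Data frame (`fpr`, `tpr`) on the grid.
#' @export
mean_roc <- function(rocs, fpr_grid = seq(0, 1, length.out = 101)) {
  stop_if_not(length(rocs) > 0, "empty ROC list")
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$fpr, r$tpr, xout = fpr_grid, rule = 2,
                  ties = max)$y
  }, numeric(length(fpr_grid)))
  data.frame(fpr = fpr_grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Recovery rate (TPR) at a fixed false positive rate
#'
#' Reads the true positive rate off a (mean) ROC curve at the requested
#' FPR by linear interpolation — the recovery rate of the target
#' population at that false-positive budget.
#'
#' @param roc ROC data frame (`fpr`, `tpr`).
#' @param fpr False positive rate in `[0, 1]`.
#' @return Interpolated TPR.
#' @export
recovery_at_fpr <- function(roc, fpr) {
  stop_if_not(is_number(fpr) && fpr >= 0 && fpr <= 1,
              "fpr must be in [0, 1]")
  stats::approx(roc$fpr, roc$tpr, xout = fpr, rule = 2, ties = max)$y
}
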