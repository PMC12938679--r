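# Classification metrics at a fixed threshold, rank-based AUC, and
# ROC-curve utilities.

#' Confusion counts and threshold metrics for one evaluation fold
#'
#' Scores at or above the threshold are predicted positive. Precision =
#' TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN), Accuracy =
#' (TP+TN)/N; AUC is the Mann-Whitney rank statistic with ties averaged.
#' Undefined ratios (empty denominators) are reported as `NA`; with a
#' single observed class the AUC is `NA` with a warning.
#'
#' @param scores Predicted positive-class probabilities in \[0, 1\].
#' @param labels Binary labels (1/`"positive"` = radiosensitive).
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `metrics_report`: `counts` (TP, TN, FP, FN),
#'   `precision`, `recall`, `f1`, `accuracy`, `auc`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  t01 <- .as01(labels)
  if (length(scores) != length(t01)) stop("scores and labels lengths differ")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & t01 == 1); tn <- sum(pred == 0 & t01 == 0)
  fp <- sum(pred == 1 & t01 == 0); fn <- sum(pred == 0 & t01 == 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    accuracy = (tp + tn) / length(t01),
    auc = auc_rank(scores, t01)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "precision %.4f | recall %.4f | F1 %.4f | accuracy %.4f | AUC %s\n",
    x$precision, x$recall, x$f1, x$accuracy,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney, ties averaged)
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUC in \[0, 1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_rank <- function(scores, labels) {
  t01 <- .as01(labels)
  n1 <- sum(t01 == 1); n0 <- sum(t01 == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single observed class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[t01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#' @param scores,labels As in [compute_metrics()].
#' @return Data frame with columns `fpr`, `tpr`, ordered by `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  t01 <- .as01(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(t01 == 1); n0 <- sum(t01 == 0)
  tpr <- vapply(thr, function(th) sum(scores >= th & t01 == 1) / n1, 0)
  fpr <- vapply(thr, function(th) sum(scores >= th & t01 == 0) / n0, 0)
  data.frame(fpr = fpr, tpr = tpr)
}

# Interpolate a fold's ROC onto a fixed FPR grid (vertical averaging).
.roc_on_grid <- function(roc, grid) {
  stats::approx(roc$fpr, roc$tpr, xout = grid, method = "linear",
                ties = max, yleft = 0, yright = 1)$y
}

#' Vertically averaged mean ROC over folds
#' @param rocs List of ROC data frames from [roc_curve()].
#' @param grid_points Number of FPR grid points (default 101).
#' @return Data frame `fpr`, `mean_tpr`.
#' @export
mean_roc <- function(rocs, grid_points = 101) {
  grid <- seq(0, 1, length.out = grid_points)
  tprs <- vapply(rocs, .roc_on_grid, numeric(grid_points), grid = grid)
  data.frame(fpr = grid, mean_tpr = rowMeans(matrix(tprs, grid_points)))
}
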