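# Stratified five-fold evaluation and the modality-ablation harness.
# All preprocessing (gene selection, clinical cleaning, standardization)
# is refitted on each training fold, so test folds never leak into
# feature selection.

#' Stratified fold assignment
#'
#' Assigns each patient a fold in 1..k, shuffling within each stratum and
#' distributing round-robin so every fold's class ratio is within one
#' patient of the global ratio.
#'
#' @param strata Vector defining the strata (e.g. labels).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids.
#' @export
stratified_folds <- function(strata, k, seed = 1) {
  if (any(table(strata) < k)) {
    stop("a stratum has fewer members than folds; cannot stratify")
  }
  folds <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated evaluation of the fusion classifier
#'
#' Stratified k-fold cross-validation: for each fold, the full pipeline is
#' fitted on the training folds via [radfusion()] and evaluated on the
#' held-out fold; every labeled patient is tested exactly once. Reports
#' per-fold and mean metrics, a vertically averaged mean ROC curve, and
#' the pooled out-of-fold scores.
#'
#' @param x A `cohort`.
#' @param modalities Modality subset, as in [radfusion()].
#' @param control A [train_control()].
#' @param seed Base seed; fold models use `seed + fold`.
#' @param folds Optional explicit fold assignment over the labeled
#'   patients (integer vector in 1..`control$folds`).
#' @return A list of class `cv_result`: `per_fold` (list of
#'   `metrics_report`), `mean` (named vector averaging the defined per-fold
#'   metrics), `roc` (mean ROC data frame), `oof` (data frame with
#'   patient_id, fold, score, label), and `fold_assignment`.
#' @export
cross_validate <- function(x, modalities = c("I", "G", "R"),
                           control = train_control(), seed = control$seed,
                           folds = NULL) {
  xl <- labeled_cohort(x)
  n <- length(xl$patient_id)
  if (length(unique(xl$label)) < 2L) stop("cohort needs both classes")
  if (is.null(folds)) {
    folds <- stratified_folds(xl$label, control$folds, seed = seed)
  }
  stopifnot(length(folds) == n)
  k <- max(folds)
  per_fold <- vector("list", k)
  rocs <- vector("list", k)
  oof <- data.frame(patient_id = xl$patient_id, fold = folds,
                    score = NA_real_, label = xl$label,
                    stringsAsFactors = FALSE)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    train <- xl[folds != f]
    test <- xl[folds == f]
    fit <- radfusion(train, modalities = modalities, control = control,
                     seed = seed + f)
    sc <- predict(fit, test)
    oof$score[folds == f] <- sc
    per_fold[[f]] <- compute_metrics(sc, test$label,
                                     threshold = control$threshold)
    rocs[[f]] <- roc_curve(sc, test$label)
    fits[[f]] <- fit
  }
  metric_names <- c("precision", "recall", "f1", "accuracy", "auc")
  mean_metrics <- vapply(metric_names, function(mn) {
    vals <- vapply(per_fold, `[[`, 0, mn)
    mean(vals, na.rm = TRUE)
  }, 0)
  structure(list(per_fold = per_fold, mean = mean_metrics,
                 roc = mean_roc(rocs), oof = oof,
                 fold_assignment = folds, fits = fits,
                 modalities = modalities),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, modalities {%s}\n",
              length(x$per_fold), paste(x$modalities, collapse = ", ")))
  cat("mean metrics:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Modality-ablation evaluation
#'
#' Re-runs the cross-validated evaluation with only the named modalities;
#' absent modalities are removed from the fusion token sequence entirely
#' (not zero-filled). `c("I", "G", "R")` reproduces the full model.
#'
#' @param x A `cohort`.
#' @param modalities Non-empty subset of `c("I", "G", "R")`.
#' @param control A [train_control()].
#' @param seed Base seed.
#' @param folds Optional explicit fold assignment (shared across ablation
#'   arms for paired comparisons).
#' @return A `cv_result`.
#' @export
ablation <- function(x, modalities, control = train_control(),
                     seed = control$seed, folds = NULL) {
  if (length(modalities) == 0L) stop("modality subset must be non-empty")
  cross_validate(x, modalities = modalities, control = control, seed = seed,
                 folds = folds)
}

#' Out-of-fold risk scores from the survival-head model
#'
#' Cross-validates the risk-head variant: per fold, the pipeline is fitted
#' with the Cox partial-likelihood head on the training folds and scalar
#' risk scores are predicted for the held-out patients. Folds are
#' stratified on the event indicator. All patients with at least 30 days
#' of follow-up participate.
#'
#' @param x A `cohort`.
#' @param modalities Modality subset.
#' @param control A [train_control()].
#' @param seed Base seed.
#' @return Data frame with `patient_id`, `fold`, `risk`, `time`, `event`.
#' @export
cv_risk_scores <- function(x, modalities = c("I", "G", "R"),
                           control = train_control(), seed = control$seed) {
  xs <- x[x$survival_days >= 30]
  folds <- stratified_folds(xs$event, control$folds, seed = seed)
  out <- data.frame(patient_id = xs$patient_id, fold = folds,
                    risk = NA_real_, time = xs$survival_days,
                    event = xs$event, stringsAsFactors = FALSE)
  for (f in seq_len(max(folds))) {
    fit <- radfusion(xs[folds != f], modalities = modalities,
                     head_type = "risk", control = control, seed = seed + f)
    out$risk[folds == f] <- predict(fit, xs[folds == f])
  }
  out
}
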