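# Survival-task evaluation: Kaplan-Meier curves, two-sample log-rank test,
# and median risk-score stratification of out-of-fold predictions.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function under right censoring,
#' reported as a step function over the distinct event times.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event).
#' @return A data frame of class `km_curve` with columns `time`,
#'   `n_risk`, `n_event`, `survival`, restricted to event times. With no
#'   events the curve is constant at 1 (zero rows).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                       n_event = fit$n.event[keep],
                       survival = fit$surv[keep]),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve A `km_curve`.
#' @param at Times at which to read off the survival probability.
#' @return Survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, 0)
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square statistic (1 df, hypergeometric variance)
#' comparing the survival distributions of two groups, with the p-value
#' from the upper chi-square tail.
#'
#' @param time,event Survival outcome.
#' @param group Two-level grouping vector.
#' @return A list of class `logrank_test` with `statistic`, `p_value`,
#'   `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  if (all(event == 0)) {
    # no events: no information, statistic 0 by convention
    return(structure(list(statistic = 0, p_value = 1,
                          n = table(group)), class = "logrank_test"))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(statistic = unname(fit$chisq),
                 p_value = stats::pchisq(fit$chisq, df = 1,
                                         lower.tail = FALSE),
                 n = fit$n),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f (1 df), p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Median risk stratification with Kaplan-Meier curves and log-rank test
#'
#' Computes out-of-fold risk scores for every patient via the survival-head
#' model ([cv_risk_scores()]), splits the pooled scores at their median
#' (ties at the median assigned to the low-risk group), and compares the
#' two groups' survival by Kaplan-Meier estimation and the log-rank test.
#' Any strictly monotone transform of the scores yields the identical
#' stratification.
#'
#' @param x A `cohort`.
#' @param modalities Modality subset.
#' @param control A [train_control()].
#' @param seed Base seed.
#' @param risk Optional precomputed data frame with columns `risk`, `time`,
#'   `event` (e.g. from [cv_risk_scores()]); when supplied no models are
#'   fitted.
#' @return A list of class `km_stratification`: `risk` (the score table
#'   with a `group` column), `curves` (named list of `km_curve`),
#'   `logrank`, and `median`.
#' @export
stratify_and_test <- function(x = NULL, modalities = c("I", "G", "R"),
                              control = train_control(),
                              seed = control$seed, risk = NULL) {
  if (is.null(risk)) {
    risk <- cv_risk_scores(x, modalities = modalities, control = control,
                           seed = seed)
  }
  if (length(unique(risk$risk)) == 1L) {
    stop("all risk scores identical; median split undefined")
  }
  med <- stats::median(risk$risk)
  risk$group <- ifelse(risk$risk > med, "high", "low")
  if (!all(c("high", "low") %in% risk$group)) {
    stop("median split produced an empty group")
  }
  curves <- lapply(split(risk, risk$group), function(d) {
    km_estimate(d$time, d$event)
  })
  lr <- logrank_test(risk$time, risk$event, risk$group)
  structure(list(risk = risk, curves = curves, logrank = lr, median = med),
            class = "km_stratification")
}

#' @export
print.km_stratification <- function(x, ...) {
  cat(sprintf("median risk split: %d high-risk / %d low-risk\n",
              sum(x$risk$group == "high"), sum(x$risk$group == "low")))
  print(x$logrank)
  invisible(x)
}

#' Plot the stratified Kaplan-Meier curves
#' @param x A `km_stratification`.
#' @param ... Passed to [plot()].
#' @export
plot.km_stratification <- function(x, ...) {
  xmax <- max(x$risk$time)
  plot(NULL, xlim = c(0, xmax), ylim = c(0, 1), xlab = "days",
       ylab = "survival probability", main = "risk-stratified survival", ...)
  cols <- c(high = "firebrick", low = "steelblue")
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)),
                    do.points = FALSE, col = cols[[g]])
  }
  graphics::legend("bottomleft", legend = sprintf(
    "%s risk (n=%d)", names(x$curves),
    vapply(names(x$curves), function(g) sum(x$risk$group == g), 0L)),
    col = cols[names(x$curves)], lty = 1, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.2g", x$logrank$p_value), side = 3)
  invisible(x)
}

#' Write stratification outputs to files
#' @param x A `km_stratification`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
save_km_stratification <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(names(x$curves), function(g) {
    cbind(group = g, x$curves[[g]])
  }))
  write_tsv_exact(tab, file.path(dir, "km_curves.tsv"))
  jsonlite::write_json(
    list(statistic = x$logrank$statistic, p_value = x$logrank$p_value,
         n_high = sum(x$risk$group == "high"),
         n_low = sum(x$risk$group == "low")),
    file.path(dir, "logrank.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, c("km_curves.tsv", "logrank.json")))
}
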