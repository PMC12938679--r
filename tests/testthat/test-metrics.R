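test_that("class weights are inverse class proportions", {
  # head-and-neck-like composition: 149 positive / 51 negative of 200
  labels <- c(rep("positive", 149), rep("negative", 51))
  w <- class_weights(labels)
  expect_equal(w[["positive"]], 200 / 149, tolerance = 1e-12)
  expect_equal(w[["negative"]], 200 / 51, tolerance = 1e-12)
  # balanced case
  wb <- class_weights(rep(c(0, 1), 25))
  expect_equal(unname(wb), c(2, 2))
  # breast-like composition: weight ratio equals the imbalance ratio
  w2 <- class_weights(c(rep(1, 239), rep(0, 43)))
  expect_equal(w2[["negative"]] / w2[["positive"]], 239 / 43,
               tolerance = 1e-12)
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("weighted loss evaluates its defining formula", {
  # perfect prediction costs nothing
  expect_equal(weighted_loss(1, 1, 5), 0, tolerance = 1e-10)
  # hand value: p = 0.5, t = 1, w = 2, N = 1 -> 2 ln 2
  expect_equal(weighted_loss(0.5, 1, 2), 2 * log(2), tolerance = 1e-12)
  expect_error(weighted_loss(c(0.5, 0.5), 1), "lengths differ")
})

test_that("unit weights reduce the weighted loss to plain cross-entropy", {
  with_seed(1, {
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      p <- runif(n, 0.01, 0.99)
      t <- rbinom(n, 1, 0.5)
      plain <- -mean(t * log(p) + (1 - t) * log(1 - p))
      expect_equal(weighted_loss(p, t, 1), plain, tolerance = 1e-12)
    }
  })
})

test_that("threshold metrics match arithmetic on the confusion table", {
  # TP=8 FP=2 FN=1 TN=5
  scores <- c(rep(0.9, 8), rep(0.1, 1), rep(0.9, 2), rep(0.1, 5))
  labels <- c(rep(1, 9), rep(0, 7))
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m$counts), c(8, 5, 2, 1))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 16 / 19)
  expect_equal(m$accuracy, 13 / 16)
  # scores at the threshold count as positive predictions
  m2 <- compute_metrics(c(0.5, 0.49), c(1, 0))
  expect_equal(unname(m2$counts), c(1, 1, 0, 0))
})

test_that("metric identities hold over exhaustive small confusion tables", {
  # brute-force counting over all tables with entries <= 6 (the formulas
  # are ratios of counts, so the property extends to larger entries);
  # accumulate the worst deviation and assert once
  worst <- 0; counts_ok <- TRUE
  for (tp in 0:6) for (fp in 0:6) for (fn in 0:6) for (tn in 0:6) {
    n <- tp + fp + fn + tn
    if (n == 0 || tp + fn == 0 || tn + fp == 0) next
    scores <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
    labels <- c(rep(1, tp + fn), rep(0, fp + tn))
    m <- suppressWarnings(compute_metrics(scores, labels))
    counts_ok <- counts_ok && identical(unname(m$counts),
                                        c(tp, tn, fp, fn))
    dev <- abs(m$recall - tp / (tp + fn))
    dev <- max(dev, abs(m$accuracy - (tp + tn) / n))
    if (tp + fp > 0) dev <- max(dev, abs(m$precision - tp / (tp + fp)))
    if (tp > 0) {
      # F1 equals the harmonic mean of precision and recall when defined
      dev <- max(dev, abs(m$f1 - 2 * m$precision * m$recall /
                            (m$precision + m$recall)))
    }
    worst <- max(worst, dev)
  }
  expect_true(counts_ok)
  expect_lt(worst, 1e-12)
})

test_that("perfect separation yields all metrics 1", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c(m$precision, m$recall, m$f1, m$accuracy, m$auc),
               rep(1, 5))
})

test_that("AUC is a rank statistic: tie-averaged, transform-invariant,
           null-centred", {
  with_seed(3, {
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.4)
  })
  a <- auc_rank(scores, labels)
  # invariant under strictly monotone transforms
  expect_equal(auc_rank(plogis(5 * scores - 2), labels), a)
  expect_equal(auc_rank(rank(scores), labels), a)
  # independent scores: AUC ~ 0.5 within 3 SE
  n1 <- sum(labels); n0 <- sum(1 - labels)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * se)
  # cross-check against an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(
      labels, scores, quiet = TRUE, direction = "<",
      levels = c("0", "1")))), tolerance = 1e-12)
  }
  # single-class input: NA with warning
  expect_warning(av <- auc_rank(scores, rep(1, 200)), "single")
  expect_true(is.na(av))
})

test_that("mean ROC vertically averages fold curves on a fixed grid", {
  r1 <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  r2 <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  m <- mean_roc(list(r1, r2), grid_points = 5)
  expect_equal(m$fpr, seq(0, 1, 0.25))
  expect_equal(m$mean_tpr, (c(0, 0.5, 1, 1, 1) + c(0, 0.25, 0.5, 0.75, 1)) / 2)
})
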