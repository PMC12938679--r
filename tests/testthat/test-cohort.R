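test_that("derive_label implements the five-year / 30-day rules", {
  # >5y survivor positive; sub-30-day excluded; death within 5y negative;
  # censored before cutoff excluded
  expect_identical(derive_label(c(2000, 20, 400, 1000), c(1, 1, 1, 0)),
                   c("positive", "excluded", "negative", "excluded"))
  # boundary: death at exactly 1825 days is within five years
  expect_identical(derive_label(1825, 1), "negative")
  expect_identical(derive_label(1826, 0), "positive")
  # survival observed past cutoff suffices even without an event
  expect_identical(derive_label(3000, 0), "positive")
  # sensitivity-analysis policy flips censored-before-cutoff to positive
  expect_identical(derive_label(1000, 0, censored_policy = "positive"),
                   "positive")
  expect_error(derive_label(-1, 1), "non-negative")
  expect_error(derive_label(100, 2), "event")
})

test_that("derive_label is monotone in survival for observed deaths", {
  days <- sort(c(0, 29, 30, 400, 1825, 1826, 4000, runif(50, 0, 4000)))
  labs <- derive_label(days, rep(1, length(days)))
  ord <- match(labs, c("excluded", "negative", "positive"))
  # once survival is long enough to be positive it never reverts
  expect_true(all(diff(ord[ord != 1]) >= 0))
  # every record gets exactly one label
  expect_true(all(labs %in% c("positive", "negative", "excluded")))
})

test_that("cohort construction validates alignment and label consistency", {
  coh <- make_test_cohort(n = 20)
  expect_s3_class(coh, "cohort")
  expect_identical(coh$label,
                   derive_label(coh$survival_days, coh$event))
  expect_error(
    cohort(c("a", "a"), c(100, 200), c(1, 1),
           matrix(0, 2, 3), matrix(0, 2, 2), data.frame(x = 1:2)),
    "duplicate")
  expect_error(
    cohort(c("a", "b"), c(100, 200), c(1, 1),
           matrix(0, 3, 3), matrix(0, 2, 2), data.frame(x = 1:2)),
    "patient count")
})

test_that("save/load round-trips cohorts exactly, including unicode ids", {
  for (seed in 1:3) {
    coh <- make_test_cohort(n = 15, seed = seed)
    coh$patient_id[1] <- "пациент-α"           # exercised through files
    coh <- cohort(coh$patient_id, coh$survival_days, coh$event,
                  coh$embedding, coh$expression, coh$clinical,
                  expression_ref = coh$expression_ref)
    dir <- withr::local_tempdir()
    save_cohort(coh, dir)
    re <- suppressMessages(load_cohort(
      file.path(dir, "clinical.tsv"), file.path(dir, "expression.tsv"),
      file.path(dir, "embeddings.tsv"), file.path(dir, "survival.tsv")))
    expect_identical(re$patient_id, coh$patient_id)
    expect_identical(re$survival_days, coh$survival_days)
    expect_identical(re$event, coh$event)
    expect_identical(re$label, coh$label)
    expect_equal(unname(re$embedding), unname(coh$embedding),
                 tolerance = 0)
    expect_equal(re$expression, coh$expression, tolerance = 0,
                 ignore_attr = FALSE)
    expect_identical(re$gene_ids, coh$gene_ids)
    expect_equal(re$expression_ref, coh$expression_ref, tolerance = 0)
    expect_equal(re$clinical$age, coh$clinical$age)
  }
})

test_that("load_cohort restricts to the modality intersection", {
  coh <- make_test_cohort(n = 4)
  dir <- withr::local_tempdir()
  save_cohort(coh, dir)
  # drop one patient from the expression file only
  expr <- read.delim(file.path(dir, "expression.tsv"), check.names = FALSE)
  write.table(expr[-2, ], file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  re <- suppressMessages(load_cohort(
    file.path(dir, "clinical.tsv"), file.path(dir, "expression.tsv"),
    file.path(dir, "embeddings.tsv"), file.path(dir, "survival.tsv")))
  expect_length(re$patient_id, 3)
  expect_false("P2" %in% re$patient_id)
})

test_that("saving an empty cohort errors and short survivors are excluded", {
  coh <- make_test_cohort(n = 12)
  expect_error(save_cohort(coh[integer(0)], withr::local_tempdir()))
  # inject a 10-day survivor via the files
  dir <- withr::local_tempdir()
  save_cohort(coh, dir)
  surv <- read.delim(file.path(dir, "survival.tsv"))
  surv$survival_days[1] <- 10
  write.table(surv, file.path(dir, "survival.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  re <- suppressMessages(load_cohort(
    file.path(dir, "clinical.tsv"), file.path(dir, "expression.tsv"),
    file.path(dir, "embeddings.tsv"), file.path(dir, "survival.tsv")))
  expect_identical(re$label[re$patient_id == "P1"], "excluded")
})

test_that("labeled_cohort and subsetting preserve alignment", {
  coh <- make_test_cohort(n = 30, seed = 4)
  xl <- labeled_cohort(coh)
  expect_true(all(xl$label != "excluded"))
  sub <- coh[3:7]
  expect_identical(sub$patient_id, coh$patient_id[3:7])
  expect_identical(unname(sub$expression), unname(coh$expression[3:7, ]))
})
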