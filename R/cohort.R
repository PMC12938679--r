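# Cohort container, radiosensitivity labeling rules, and cohort file I/O.
#
# A cohort aligns, per patient: a slide-level pathology embedding (produced
# upstream by a frozen foundation encoder and consumed here as a numeric
# vector), a gene-expression profile, raw clinical variables, and the
# survival outcome (days + event indicator). The radiosensitivity label is
# derived from the survival outcome.

#' Derive the radiosensitivity label from a survival outcome
#'
#' Patients surviving beyond the cutoff (default five years = 1825 days) are
#' labeled `"positive"` (radiosensitive) whether or not death was eventually
#' observed; patients who died within the cutoff are `"negative"`; patients
#' with follow-up shorter than `min_days` are `"excluded"` to avoid deaths
#' from unrelated causes. Patients censored before the cutoff cannot be
#' assigned either class without immortal-time bias and are excluded by
#' default; set `censored_policy = "positive"` for a sensitivity analysis
#' that treats them as survivors.
#'
#' @param survival_days Non-negative numeric vector of follow-up times in days.
#' @param event Integer vector in \{0, 1\}; 1 = death observed, 0 = censored.
#' @param years_cutoff Cutoff in years separating positive from negative
#'   (default 5; a year is 365 days).
#' @param min_days Minimum follow-up in days; shorter survivors are excluded
#'   (default 30).
#' @param censored_policy How to label patients censored at or before the
#'   cutoff: `"exclude"` (default) or `"positive"`.
#' @return Character vector with values in `c("positive", "negative",
#'   "excluded")`.
#' @examples
#' derive_label(c(2000, 20, 400, 1000), c(1, 1, 1, 0))
#' @export
derive_label <- function(survival_days, event, years_cutoff = 5,
                         min_days = 30,
                         censored_policy = c("exclude", "positive")) {
  censored_policy <- match.arg(censored_policy)
  if (any(is.na(survival_days)) || any(survival_days < 0)) {
    stop("survival_days must be non-negative and non-missing")
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (length(event) != length(survival_days)) {
    stop("survival_days and event lengths differ")
  }
  cutoff <- years_cutoff * 365
  label <- rep("excluded", length(survival_days))
  label[survival_days > cutoff] <- "positive"
  label[event == 1 & survival_days <= cutoff] <- "negative"
  if (censored_policy == "positive") {
    label[event == 0 & survival_days <= cutoff] <- "positive"
  }
  label[survival_days < min_days] <- "excluded"
  label
}

#' Construct a cohort object
#'
#' Validates and assembles aligned per-patient modalities into a `cohort`
#' object. Matrices are oriented patients x features throughout.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param survival_days,event Survival outcome per patient.
#' @param embedding Numeric matrix (patients x `d_img`) of slide-level
#'   pathology embeddings.
#' @param expression Numeric matrix (patients x genes); column names are the
#'   gene identifiers.
#' @param clinical Data frame of raw clinical variables (may contain `NA`),
#'   one row per patient, without a patient_id column.
#' @param expression_ref Optional reference expression matrix with the same
#'   shape and gene columns, giving the contrast group for the
#'   differential-expression screen (e.g. pre-treatment profiles).
#' @param label Optional character labels; recomputed from the outcome via
#'   [derive_label()] when omitted.
#' @param censored_policy Passed to [derive_label()].
#' @return An object of class `cohort`: a list with elements `patient_id`,
#'   `survival_days`, `event`, `label`, `embedding`, `expression`,
#'   `clinical`, `gene_ids`, `d_img`, and optionally `expression_ref`.
#' @export
cohort <- function(patient_id, survival_days, event, embedding, expression,
                   clinical, expression_ref = NULL, label = NULL,
                   censored_policy = "exclude") {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  embedding <- as.matrix(embedding)
  expression <- as.matrix(expression)
  if (nrow(embedding) != n || nrow(expression) != n || nrow(clinical) != n) {
    stop("modalities disagree on patient count")
  }
  if (length(survival_days) != n || length(event) != n) {
    stop("survival outcome length mismatch")
  }
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("gene_", seq_len(ncol(expression)))
  }
  if (!is.null(expression_ref)) {
    expression_ref <- as.matrix(expression_ref)
    if (!identical(dim(expression_ref), dim(expression)) ||
        !identical(colnames(expression_ref), colnames(expression))) {
      stop("expression_ref must match expression in shape and gene columns")
    }
  }
  derived <- derive_label(survival_days, event,
                          censored_policy = censored_policy)
  if (is.null(label)) {
    label <- derived
  } else if (!identical(as.character(label), derived)) {
    stop("supplied labels are inconsistent with derive_label()")
  }
  rownames(embedding) <- rownames(expression) <- patient_id
  if (!is.null(expression_ref)) rownames(expression_ref) <- patient_id
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  rownames(clinical) <- patient_id
  structure(
    list(patient_id = patient_id,
         survival_days = as.numeric(survival_days),
         event = as.integer(event),
         label = label,
         embedding = embedding,
         expression = expression,
         expression_ref = expression_ref,
         clinical = clinical,
         gene_ids = colnames(expression),
         d_img = ncol(embedding)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$label, c("positive", "negative", "excluded")))
  cat(sprintf(
    "cohort: %d patients, %d genes, %d-dim embeddings, %d clinical variables\n",
    length(x$patient_id), length(x$gene_ids), x$d_img, ncol(x$clinical)))
  cat(sprintf("labels: %d positive / %d negative / %d excluded\n",
              tab[["positive"]], tab[["negative"]], tab[["excluded"]]))
  invisible(x)
}

#' Subset a cohort by patient index
#' @param x A `cohort`.
#' @param i Integer or logical index over patients.
#' @param ... Ignored.
#' @return A `cohort` restricted to the selected patients.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$patient_id[i], x$survival_days[i], x$event[i],
         x$embedding[i, , drop = FALSE], x$expression[i, , drop = FALSE],
         x$clinical[i, , drop = FALSE],
         expression_ref = if (!is.null(x$expression_ref))
           x$expression_ref[i, , drop = FALSE])
}

#' Keep only labeled (non-excluded) patients
#' @param x A `cohort`.
#' @return A `cohort` containing only positive- and negative-labeled patients.
#' @export
labeled_cohort <- function(x) x[x$label != "excluded"]

#' Write a cohort to a directory of plain-text tables
#'
#' Writes `clinical.tsv`, `expression.tsv`, `survival.tsv`, `embeddings.tsv`
#' (a bare matrix with a sidecar `embeddings_patients.txt` listing the row
#' order), and `expression_ref.tsv` when present. Numeric values are written
#' with 17 significant digits so that [load_cohort()] inverts the save
#' exactly.
#'
#' @param x A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
save_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  if (length(x$patient_id) == 0L) stop("refusing to save an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  clin <- cbind(data.frame(patient_id = x$patient_id,
                           stringsAsFactors = FALSE), x$clinical)
  write_tsv_exact(clin, file.path(dir, "clinical.tsv"))

  expr <- cbind(data.frame(patient_id = x$patient_id,
                           stringsAsFactors = FALSE),
                as.data.frame(x$expression, check.names = FALSE))
  write_tsv_exact(expr, file.path(dir, "expression.tsv"))

  surv <- data.frame(patient_id = x$patient_id,
                     survival_days = x$survival_days, event = x$event,
                     stringsAsFactors = FALSE)
  write_tsv_exact(surv, file.path(dir, "survival.tsv"))

  emb <- as.data.frame(x$embedding, check.names = FALSE)
  colnames(emb) <- paste0("dim_", seq_len(ncol(emb)))
  write_tsv_exact(emb, file.path(dir, "embeddings.tsv"))
  writeLines(x$patient_id, file.path(dir, "embeddings_patients.txt"),
             useBytes = FALSE)

  files <- c("clinical.tsv", "expression.tsv", "survival.tsv",
             "embeddings.tsv", "embeddings_patients.txt")
  if (!is.null(x$expression_ref)) {
    er <- cbind(data.frame(patient_id = x$patient_id,
                           stringsAsFactors = FALSE),
                as.data.frame(x$expression_ref, check.names = FALSE))
    write_tsv_exact(er, file.path(dir, "expression_ref.tsv"))
    files <- c(files, "expression_ref.tsv")
  }
  invisible(file.path(dir, files))
}

#' Load a cohort from modality files
#'
#' Reads the four modality tables, restricts to patients present in every
#' file, derives labels, and reports the number of patients dropped at the
#' intersection step and excluded by the labeling rules.
#'
#' @param clinical_path TSV with a header and first column `patient_id`;
#'   missing values as empty strings or `NA`.
#' @param expression_path TSV, first column `patient_id`, remaining columns
#'   one per gene.
#' @param embedding_path TSV matrix of embeddings without an id column; the
#'   patient order is read from a sidecar file named
#'   `<stem>_patients.txt` next to it (or pass `embedding_patients_path`).
#' @param survival_path TSV with columns `patient_id`, `survival_days`,
#'   `event`.
#' @param embedding_patients_path Optional explicit sidecar path.
#' @param censored_policy Passed to [derive_label()].
#' @return A `cohort`.
#' @export
load_cohort <- function(clinical_path, expression_path, embedding_path,
                        survival_path, embedding_patients_path = NULL,
                        censored_policy = "exclude") {
  for (p in c(clinical_path, expression_path, embedding_path, survival_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  clin <- read_tsv_utf8(clinical_path, na.strings = c("NA", ""))
  expr <- read_tsv_utf8(expression_path)
  surv <- read_tsv_utf8(survival_path)
  if (is.null(embedding_patients_path)) {
    embedding_patients_path <- file.path(
      dirname(embedding_path),
      paste0(sub("\\.[^.]*$", "", basename(embedding_path)), "_patients.txt"))
  }
  if (!file.exists(embedding_patients_path)) {
    stop("embedding patient-order sidecar not found: ",
         embedding_patients_path)
  }
  emb <- as.matrix(read_tsv_utf8(embedding_path))
  emb_ids <- readLines(embedding_patients_path, encoding = "UTF-8")
  if (length(emb_ids) != nrow(emb)) {
    stop("embedding sidecar length disagrees with embedding rows")
  }

  ids_list <- list(as.character(clin[[1L]]), as.character(expr[[1L]]),
                   emb_ids, as.character(surv[[1L]]))
  for (ids in ids_list) {
    if (anyDuplicated(ids)) stop("duplicate patient ids in an input file")
  }
  keep <- Reduce(intersect, ids_list)
  if (length(keep) == 0L) stop("no patients shared across all modality files")
  n_union <- length(Reduce(union, ids_list))
  message(sprintf("load_cohort: %d patients in all modalities (%d dropped)",
                  length(keep), n_union - length(keep)))

  rownames(clin) <- as.character(clin[[1L]])
  rownames(expr) <- as.character(expr[[1L]])
  rownames(surv) <- as.character(surv[[1L]])
  rownames(emb) <- emb_ids

  surv <- surv[keep, , drop = FALSE]
  expr_ref_path <- file.path(dirname(expression_path), "expression_ref.tsv")
  expr_ref <- NULL
  if (file.exists(expr_ref_path)) {
    er <- read_tsv_utf8(expr_ref_path)
    rownames(er) <- as.character(er[[1L]])
    expr_ref <- as.matrix(er[keep, -1L, drop = FALSE])
  }
  out <- cohort(
    patient_id = keep,
    survival_days = surv$survival_days,
    event = surv$event,
    embedding = emb[keep, , drop = FALSE],
    expression = as.matrix(expr[keep, -1L, drop = FALSE]),
    clinical = clin[keep, -1L, drop = FALSE],
    expression_ref = expr_ref,
    censored_policy = censored_policy
  )
  message(sprintf("load_cohort: labels %d positive / %d negative / %d excluded",
                  sum(out$label == "positive"), sum(out$label == "negative"),
                  sum(out$label == "excluded")))
  out
}
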