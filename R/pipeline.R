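# End-to-end pipeline: simulate -> select genes -> train/evaluate ->
# ablate -> survival stratification -> report, with a manifest per stage.

.stage_manifest <- function(dir, stage, config, seed, files) {
  hashes <- vapply(files, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, "")
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         package_version = as.character(utils::packageVersion("radfusion")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, files = as.list(hashes)),
    file.path(dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

.metrics_as_list <- function(cv) {
  list(
    per_fold = lapply(cv$per_fold, function(m) {
      c(as.list(m$counts),
        list(precision = m$precision, recall = m$recall, f1 = m$f1,
             accuracy = m$accuracy, auc = m$auc))
    }),
    mean = as.list(cv$mean)
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation (or loading of a previously saved
#' cohort directory), gene selection on the full labeled cohort (reported
#' for inspection; cross-validation refits it per training fold),
#' cross-validated training and evaluation, modality ablation, survival
#' stratification, and a JSON report. Each stage writes its outputs and a
#' manifest under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param gen_config A [generator_config()] (ignored when `cohort_dir` is
#'   given).
#' @param control A [train_control()].
#' @param cohort_dir Optional directory of cohort files from
#'   [save_cohort()] to use instead of simulating.
#' @param ablation_sets List of modality subsets to ablate (default: the
#'   three unimodal arms and the full model).
#' @param seed Base seed for every stage.
#' @return Invisibly, a list with the cohort, cv result, ablation results
#'   and stratification.
#' @export
run_pipeline <- function(out_dir, gen_config = generator_config(),
                         control = train_control(), cohort_dir = NULL,
                         ablation_sets = list("I", "G", "R",
                                              c("I", "G", "R")),
                         seed = control$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage: simulate / load
  if (is.null(cohort_dir)) {
    gen_config$seed <- seed
    coh <- generate_cohort(gen_config)
    cdir <- file.path(out_dir, "cohort")
    files <- save_cohort(coh, cdir)
    gt <- attr(coh, "ground_truth")
    jsonlite::write_json(
      list(prognostic_genes = gt$prognostic_genes, beta = gt$beta,
           lambda0 = gt$lambda0, lambda_c = gt$lambda_c),
      file.path(cdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    .stage_manifest(out_dir, "simulate", unclass(gen_config), seed, files)
  } else {
    coh <- load_cohort(file.path(cohort_dir, "clinical.tsv"),
                       file.path(cohort_dir, "expression.tsv"),
                       file.path(cohort_dir, "embeddings.tsv"),
                       file.path(cohort_dir, "survival.tsv"))
    .stage_manifest(out_dir, "load", list(cohort_dir = cohort_dir), seed,
                    character())
  }

  # stage: gene selection on the labeled cohort (diagnostic artifact)
  gs_dir <- file.path(out_dir, "gene_selection")
  gs <- select_radiosensitivity_genes(
    labeled_cohort(coh), k = control$k_genes, alpha_de = control$alpha_de,
    alpha_cox = control$alpha_cox,
    ae_spec = autoencoder_spec(1L, encoder_widths = control$ae_widths,
                               latent_dim = control$ae_latent,
                               epochs = control$ae_epochs,
                               learning_rate = control$ae_lr, seed = seed),
    out_dir = gs_dir, seed = seed)
  .stage_manifest(out_dir, "select_genes", list(k = control$k_genes), seed,
                  file.path(gs_dir, "selected_genes.txt"))

  # stage: cross-validated training
  cv <- cross_validate(coh, control = control, seed = seed)
  jsonlite::write_json(.metrics_as_list(cv),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv_exact(cv$roc, file.path(out_dir, "roc_points.tsv"))
  .stage_manifest(out_dir, "train", list(folds = control$folds,
                                         epochs = control$epochs), seed,
                  file.path(out_dir, c("metrics.json", "roc_points.tsv")))

  # stage: ablation
  abl <- lapply(ablation_sets, function(m) {
    ablation(coh, m, control = control, seed = seed)
  })
  names(abl) <- vapply(ablation_sets, paste, "", collapse = "+")
  jsonlite::write_json(lapply(abl, function(a) as.list(a$mean)),
                       file.path(out_dir, "ablation.json"),
                       auto_unbox = TRUE, digits = NA)
  .stage_manifest(out_dir, "ablate", list(sets = names(abl)), seed,
                  file.path(out_dir, "ablation.json"))

  # stage: survival stratification
  km <- stratify_and_test(coh, control = control, seed = seed)
  save_km_stratification(km, out_dir)
  .stage_manifest(out_dir, "survival", list(), seed,
                  file.path(out_dir, c("km_curves.tsv", "logrank.json")))

  # stage: report
  report <- list(
    n_patients = length(coh$patient_id),
    n_labeled = sum(coh$label != "excluded"),
    n_positive = sum(coh$label == "positive"),
    n_negative = sum(coh$label == "negative"),
    selected_genes = gs$genes,
    cv_mean = as.list(cv$mean),
    ablation_auc = lapply(abl, function(a) a$mean[["auc"]]),
    logrank_p = km$logrank$p_value)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_manifest(out_dir, "report", list(), seed,
                  file.path(out_dir, "report.json"))

  invisible(list(cohort = coh, gene_selection = gs, cv = cv,
                 ablation = abl, km = km, report = report))
}
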