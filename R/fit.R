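# The central modelling interface: radfusion() fits the full multimodal
# pipeline (gene selection, clinical cleaning/encoding, fusion network) on
# a cohort and returns a classed model object with the usual methods.

#' Training and pipeline configuration
#'
#' Collects every tunable of the pipeline in one object. Defaults follow
#' the reference protocol: Adam at learning rate 0.001 for 700 epochs,
#' decision threshold 0.5, five stratified folds, inverse-proportion class
#' weighting, a 9-gene feature vector, autoencoder widths 1024/512 with a
#' 100-unit bottleneck, and a 6-dimensional clinical representation.
#'
#' @param epochs Fusion training epochs (default 700).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param threshold Classification threshold (default 0.5).
#' @param folds Cross-validation folds (default 5).
#' @param weighted Apply inverse-proportion class weights (default `TRUE`).
#' @param seed Base seed; per-fold seeds are derived from it.
#' @param k_genes Size of the gene feature vector (default 9).
#' @param alpha_de,alpha_cox Gene-selection stage thresholds (default 0.05).
#' @param ae_widths,ae_latent,ae_epochs,ae_lr Autoencoder architecture and
#'   training settings.
#' @param missing_threshold,variance_threshold,preset Clinical cleaning
#'   settings (see [clean_clinical()]).
#' @param d_clin,clin_hidden Clinical encoder widths.
#' @param d_joint,hidden,token_mode,dropout Fusion architecture settings
#'   (see [fusion_spec()]).
#' @param weight_decay L2 penalty on fusion weights (see [train_fusion()]).
#' @return A list of class `train_control`.
#' @export
train_control <- function(epochs = 700, learning_rate = 0.001,
                          threshold = 0.5, folds = 5, weighted = TRUE,
                          seed = 1, k_genes = 9, alpha_de = 0.05,
                          alpha_cox = 0.05, ae_widths = c(1024, 512),
                          ae_latent = 100, ae_epochs = 300, ae_lr = 0.001,
                          missing_threshold = 0.2, variance_threshold = 1e-8,
                          preset = NULL, d_clin = 6, clin_hidden = 16,
                          d_joint = 64, hidden = 64, token_mode = "2token",
                          dropout = 0, weight_decay = 0.01) {
  stopifnot(folds >= 2, threshold > 0, threshold < 1, epochs >= 1)
  structure(as.list(environment()), class = "train_control")
}

# Build the standardized modality input matrices for a fitted
# preprocessing state (prep) and a cohort.
.build_inputs <- function(prep, x) {
  inputs <- list()
  if (!is.null(prep$gs)) {
    G <- gene_features(prep$gs, x)
    inputs$G <- sweep(sweep(G, 2, prep$g_center), 2, prep$g_scale, "/")
  }
  if (!is.null(prep$clinical)) {
    tab <- apply_clinical_schema(prep$clinical, x$clinical)
    cr <- as.matrix(tab)
    inputs$C_raw <- sweep(sweep(cr, 2, prep$c_center), 2, prep$c_scale, "/")
  }
  if (!is.null(prep$p_center)) {
    inputs$P <- sweep(sweep(x$embedding, 2, prep$p_center), 2,
                      prep$p_scale, "/")
  }
  inputs
}

.std_stats <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' Fit the multimodal radiosensitivity model on a cohort
#'
#' Runs, on the supplied cohort only (so cross-validation wrappers can call
#' it per training fold without leakage): the three-stage gene selection
#' (when the gene modality is used), clinical cleaning and schema fitting
#' (clinical modality), per-feature standardization of every modality, and
#' fusion-network training with the configured head.
#'
#' For the classifier head only labeled (non-excluded) patients are used;
#' for the risk head all patients with at least 30 days of follow-up enter
#' the partial-likelihood loss.
#'
#' @param x A `cohort`.
#' @param modalities Subset of `c("I", "G", "R")`.
#' @param head_type `"classifier"` or `"risk"`.
#' @param control A [train_control()].
#' @param seed Seed override (defaults to `control$seed`).
#' @return An object of class `radfusion` with elements `model` (the
#'   trained `fusion_model`), `prep` (fitted preprocessing), `spec`,
#'   `control`, `modalities`, `head_type`, and training-cohort bookkeeping.
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(n_patients = 120, d_img = 32,
#'                                         n_genes = 60, seed = 7))
#' ctrl <- train_control(epochs = 60, ae_widths = c(32, 16), ae_latent = 8,
#'                       ae_epochs = 40)
#' fit <- radfusion(coh, control = ctrl)
#' print(fit)
#' }
#' @export
radfusion <- function(x, modalities = c("I", "G", "R"),
                      head_type = c("classifier", "risk"),
                      control = train_control(), seed = control$seed) {
  stopifnot(inherits(x, "cohort"), inherits(control, "train_control"))
  head_type <- match.arg(head_type)
  modalities <- unique(match.arg(modalities, c("I", "G", "R"),
                                 several.ok = TRUE))
  xf <- if (head_type == "classifier") labeled_cohort(x)
        else x[x$survival_days >= 30]
  if (length(xf$patient_id) < 10L) stop("too few usable patients")

  prep <- list()
  if ("G" %in% modalities) {
    ae_spec <- autoencoder_spec(
      input_dim = 1L,  # resized inside select_radiosensitivity_genes
      encoder_widths = control$ae_widths, latent_dim = control$ae_latent,
      epochs = control$ae_epochs, learning_rate = control$ae_lr,
      seed = seed)
    prep$gs <- select_radiosensitivity_genes(
      xf, k = control$k_genes, alpha_de = control$alpha_de,
      alpha_cox = control$alpha_cox, ae_spec = ae_spec, seed = seed)
    st <- .std_stats(prep$gs$G)
    prep$g_center <- st$center; prep$g_scale <- st$scale
  }
  if ("R" %in% modalities) {
    prep$clinical <- clean_clinical(
      xf$clinical, missing_threshold = control$missing_threshold,
      variance_threshold = control$variance_threshold,
      preset = control$preset)
    st <- .std_stats(as.matrix(prep$clinical$table))
    prep$c_center <- st$center; prep$c_scale <- st$scale
  }
  if ("I" %in% modalities) {
    st <- .std_stats(xf$embedding)
    prep$p_center <- st$center; prep$p_scale <- st$scale
  }

  inputs <- .build_inputs(prep, xf)
  spec <- fusion_spec(
    d_gene = if ("G" %in% modalities) ncol(inputs$G) else 0L,
    d_clin_raw = if ("R" %in% modalities) ncol(inputs$C_raw) else 0L,
    d_clin = control$d_clin, d_img = x$d_img, d_joint = control$d_joint,
    hidden = control$hidden, clin_hidden = control$clin_hidden,
    token_mode = control$token_mode, modalities = modalities,
    head_type = head_type, dropout = control$dropout, seed = seed)
  outcome <- if (head_type == "classifier") xf$label
             else list(time = xf$survival_days, event = xf$event)
  model <- train_fusion(inputs, outcome, spec, epochs = control$epochs,
                        learning_rate = control$learning_rate,
                        weighted = control$weighted,
                        weight_decay = control$weight_decay, seed = seed)
  structure(list(model = model, prep = prep, spec = spec, control = control,
                 modalities = modalities, head_type = head_type,
                 train_ids = xf$patient_id, train_inputs = inputs,
                 n_train = length(xf$patient_id), seed = seed),
            class = "radfusion")
}

#' Predict radiosensitivity for a cohort
#' @param object A fitted `radfusion` model.
#' @param newdata A `cohort` (defaults to the training inputs).
#' @param ... Ignored.
#' @return Positive-class probabilities (classifier head) or risk scores
#'   (risk head), named by patient id.
#' @export
predict.radfusion <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    inputs <- object$train_inputs
    ids <- object$train_ids
  } else {
    stopifnot(inherits(newdata, "cohort"))
    inputs <- .build_inputs(object$prep, newdata)
    ids <- newdata$patient_id
  }
  stats::setNames(predict(object$model, inputs), ids)
}

#' @export
print.radfusion <- function(x, ...) {
  cat(sprintf(
    "radfusion %s model: modalities {%s}, %s tokens, trained on %d patients\n",
    x$head_type, paste(x$modalities, collapse = ", "),
    length(x$spec$tokens), x$n_train))
  cat(sprintf("final training loss: %.4f\n",
              x$model$loss_trace[length(x$model$loss_trace)]))
  invisible(x)
}

#' @export
summary.radfusion <- function(object, ...) {
  att <- extract_modality_attention(object$model, object$train_inputs)
  out <- list(head_type = object$head_type,
              modalities = object$modalities,
              n_train = object$n_train,
              class_weights = object$model$class_wts,
              attention_mean = att$mean,
              genes = if (!is.null(object$prep$gs)) object$prep$gs$genes,
              clinical_variables = if (!is.null(object$prep$clinical))
                names(object$prep$clinical$schema),
              final_loss = object$model$loss_trace[
                length(object$model$loss_trace)])
  class(out) <- "summary.radfusion"
  out
}

#' @export
print.summary.radfusion <- function(x, ...) {
  cat(sprintf("radfusion %s model (modalities: %s; n = %d)\n",
              x$head_type, paste(x$modalities, collapse = ", "), x$n_train))
  if (!is.null(x$genes)) {
    cat("selected genes:", paste(x$genes, collapse = ", "), "\n")
  }
  if (!is.null(x$clinical_variables)) {
    cat("clinical variables:", paste(x$clinical_variables, collapse = ", "),
        "\n")
  }
  if (!is.null(x$class_weights)) {
    cat(sprintf("class weights: negative %.3f, positive %.3f\n",
                x$class_weights[["negative"]], x$class_weights[["positive"]]))
  }
  cat("mean attention per modality token:\n")
  print(round(x$attention_mean, 4))
  cat(sprintf("final training loss: %.4f\n", x$final_loss))
  invisible(x)
}

#' Learnable modality-reweighting coefficients
#' @param object A fitted `radfusion` model.
#' @param ... Ignored.
#' @return The reweighting matrix (tokens x latent width) applied
#'   element-wise after self-attention, with token names as row names.
#' @export
coef.radfusion <- function(object, ...) {
  rw <- object$model$params$rw
  rownames(rw) <- vapply(object$spec$tokens, `[[`, "", "name")
  rw
}

#' Plot the training loss trace
#' @param x A fitted `radfusion` model.
#' @param ... Passed to [plot()].
#' @export
plot.radfusion <- function(x, ...) {
  plot(x$model$loss_trace, type = "l", xlab = "epoch",
       ylab = "training loss",
       main = sprintf("radfusion %s training", x$head_type), ...)
  invisible(x)
}
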