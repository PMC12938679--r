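# Hierarchical self-attention fusion network.
#
# Modality representations (gene feature vector G, encoded clinical vector
# C, pathology embedding P) are projected into a shared latent space as a
# short token sequence, refined by single-head self-attention over the
# tokens, rescaled by a learnable element-wise reweighting vector, and fed
# through a dense head emitting either two-class softmax probabilities or a
# scalar survival-risk score. All forward/backward passes are vectorized
# over patients in base R; correctness of the analytic gradients is
# guarded by finite-difference tests.

#' Fusion model architecture
#'
#' @param d_gene Width of the gene feature vector (default 9).
#' @param d_clin_raw Number of cleaned clinical input variables (the
#'   clinical encoder maps these to `d_clin`). Ignored when the clinical
#'   modality is absent.
#' @param d_clin Width of the encoded clinical representation (default 6).
#' @param d_img Embedding width (default 768).
#' @param d_joint Shared latent width of the modality tokens (default 64).
#' @param hidden Hidden width of each projection MLP and of the head
#'   (default 64).
#' @param clin_hidden Hidden width of the clinical encoder (default 16).
#' @param token_mode `"2token"` (token 1 = joint gene+clinical projection,
#'   token 2 = image projection; modality weights directly readable) or
#'   `"3token"` (gene, clinical and image tokens projected separately).
#' @param modalities Subset of `c("I", "G", "R")`: image, gene, clinical
#'   report. Absent modalities are removed from the token sequence.
#' @param head_type `"classifier"` (two-class softmax) or `"risk"`
#'   (scalar risk score trained with a Cox partial-likelihood loss).
#' @param dropout Dropout rate on the head hidden layer during training
#'   (default 0; always disabled at evaluation).
#' @param residual Add a residual (skip) connection around the
#'   self-attention block, so each token's attended representation is its
#'   own content plus the attention-mixed context (default `TRUE`).
#' @param seed Weight-initialisation seed.
#' @return A list of class `fusion_spec`.
#' @export
fusion_spec <- function(d_gene = 9, d_clin_raw = 5, d_clin = 6, d_img = 768,
                        d_joint = 64, hidden = 64, clin_hidden = 16,
                        token_mode = c("2token", "3token"),
                        modalities = c("I", "G", "R"),
                        head_type = c("classifier", "risk"),
                        dropout = 0, residual = TRUE, seed = 1) {
  token_mode <- match.arg(token_mode)
  head_type <- match.arg(head_type)
  modalities <- unique(match.arg(modalities, c("I", "G", "R"),
                                 several.ok = TRUE))
  if (length(modalities) == 0L) stop("at least one modality is required")
  stopifnot(dropout >= 0, dropout < 1)
  spec <- structure(as.list(environment()), class = "fusion_spec")
  spec$tokens <- fusion_tokens(spec)
  spec
}

# Token layout implied by a spec: a list of branches, each naming its
# input modalities. 2-token mode merges G and R (when present) into one
# joint token; 3-token mode projects each modality separately.
fusion_tokens <- function(spec) {
  m <- spec$modalities
  if (spec$token_mode == "2token") {
    toks <- list()
    gc <- intersect(c("G", "R"), m)
    if (length(gc)) {
      nm <- if (length(gc) == 2L) "gene+clinical"
            else if (identical(gc, "G")) "gene" else "clinical"
      toks <- c(toks, list(list(name = nm, inputs = gc)))
    }
    if ("I" %in% m) toks <- c(toks, list(list(name = "image", inputs = "I")))
    toks
  } else {
    lab <- c(I = "image", G = "gene", R = "clinical")
    lapply(intersect(c("G", "R", "I"), m), function(x) {
      list(name = unname(lab[x]), inputs = x)
    })
  }
}

.branch_in_dim <- function(tok, spec) {
  sum(c(G = spec$d_gene, R = spec$d_clin, I = spec$d_img)[tok$inputs])
}

#' Initialise fusion model parameters
#' @param spec A [fusion_spec()].
#' @return Named list of parameter arrays (reweighting initialised to ones).
#' @export
fusion_init <- function(spec) {
  with_seed(spec$seed, {
    params <- list()
    if ("R" %in% spec$modalities) {
      cl <- .clin_init(clinical_encoder_spec(spec$d_clin_raw,
                                             output_dim = spec$d_clin,
                                             hidden = spec$clin_hidden))
      params <- c(params, cl)
    }
    for (b in seq_along(spec$tokens)) {
      d_in <- .branch_in_dim(spec$tokens[[b]], spec)
      params[[paste0("Wt1_", b)]] <- glorot(d_in, spec$hidden)
      params[[paste0("bt1_", b)]] <- numeric(spec$hidden)
      params[[paste0("Wt2_", b)]] <- glorot(spec$hidden, spec$d_joint)
      params[[paste0("bt2_", b)]] <- numeric(spec$d_joint)
    }
    params$Wq <- glorot(spec$d_joint, spec$d_joint)
    params$Wk <- glorot(spec$d_joint, spec$d_joint)
    params$Wv <- glorot(spec$d_joint, spec$d_joint)
    params$rw <- matrix(1, length(spec$tokens), spec$d_joint)
    out_dim <- if (spec$head_type == "classifier") 2L else 1L
    params$Wh1 <- glorot(length(spec$tokens) * spec$d_joint, spec$hidden)
    params$bh1 <- numeric(spec$hidden)
    params$Wh2 <- glorot(spec$hidden, out_dim)
    params$bh2 <- numeric(out_dim)
    params
  })
}

.check_inputs <- function(inputs, spec) {
  need <- c(I = "P", G = "G", R = "C_raw")[spec$modalities]
  dims <- c(P = spec$d_img, G = spec$d_gene, C_raw = spec$d_clin_raw)
  n <- NULL
  for (nm in need) {
    x <- inputs[[nm]]
    if (is.null(x)) stop("missing input for modality: ", nm)
    if (ncol(x) != dims[[nm]]) {
      stop(sprintf("width mismatch for %s: got %d, spec expects %d",
                   c(P = "image embedding", G = "gene features",
                     C_raw = "clinical variables")[[nm]],
                   ncol(x), dims[[nm]]))
    }
    if (!is.null(n) && nrow(x) != n) stop("modality row counts differ")
    n <- nrow(x)
  }
  n
}

#' Fusion forward pass
#'
#' @param params Parameter list from [fusion_init()] or a trained model.
#' @param spec The [fusion_spec()].
#' @param inputs List with elements `G` (patients x d_gene), `C_raw`
#'   (patients x d_clin_raw, standardized cleaned clinical variables) and
#'   `P` (patients x d_img), as required by `spec$modalities`.
#' @param training Apply dropout (when configured) with a fresh mask.
#' @return List with `probs` (classifier) or `risk` (risk head),
#'   `attention` (n x tokens x tokens array of attention weights),
#'   `tokens`, and the caches needed by the backward pass.
#' @export
fusion_forward <- function(params, spec, inputs, training = FALSE) {
  n <- .check_inputs(inputs, spec)
  d <- spec$d_joint
  nt <- length(spec$tokens)

  Cenc <- NULL; clin_cache <- NULL
  if ("R" %in% spec$modalities) {
    clin_cache <- .clin_forward(inputs$C_raw, params)
    Cenc <- clin_cache$out
  }
  branch_inputs <- lapply(spec$tokens, function(tok) {
    parts <- lapply(tok$inputs, function(mm) {
      switch(mm, G = inputs$G, R = Cenc, I = inputs$P)
    })
    do.call(cbind, parts)
  })
  tokens <- vector("list", nt); pre1 <- vector("list", nt)
  h1 <- vector("list", nt)
  for (b in seq_len(nt)) {
    pre1[[b]] <- sweep(branch_inputs[[b]] %*% params[[paste0("Wt1_", b)]],
                       2, params[[paste0("bt1_", b)]], "+")
    h1[[b]] <- relu(pre1[[b]])
    tokens[[b]] <- sweep(h1[[b]] %*% params[[paste0("Wt2_", b)]],
                         2, params[[paste0("bt2_", b)]], "+")
  }

  Q <- lapply(tokens, function(tk) tk %*% params$Wq)
  K <- lapply(tokens, function(tk) tk %*% params$Wk)
  V <- lapply(tokens, function(tk) tk %*% params$Wv)
  scale <- sqrt(d)
  S <- array(0, c(n, nt, nt))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    S[, i, j] <- rowSums(Q[[i]] * K[[j]]) / scale
  }
  A <- array(0, c(n, nt, nt))
  for (i in seq_len(nt)) {
    A[, i, ] <- softmax_rows(matrix(S[, i, ], n, nt))
  }
  O <- vector("list", nt)
  for (i in seq_len(nt)) {
    acc <- matrix(0, n, d)
    for (j in seq_len(nt)) acc <- acc + A[, i, j] * V[[j]]
    if (isTRUE(spec$residual)) acc <- acc + tokens[[i]]
    O[[i]] <- acc
  }
  Fw <- lapply(seq_len(nt), function(i) {
    sweep(O[[i]], 2, params$rw[i, ], "*")
  })
  flat <- do.call(cbind, Fw)
  pre_h <- sweep(flat %*% params$Wh1, 2, params$bh1, "+")
  h <- relu(pre_h)
  drop_mask <- NULL
  if (training && spec$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(h)) >= spec$dropout,
                        nrow(h), ncol(h)) / (1 - spec$dropout)
    h <- h * drop_mask
  }
  logits <- sweep(h %*% params$Wh2, 2, params$bh2, "+")

  out <- list(n = n, inputs = inputs, clin_cache = clin_cache,
              branch_inputs = branch_inputs, pre1 = pre1, h1 = h1,
              tokens = tokens, Q = Q, K = K, V = V, A = A, O = O, Fw = Fw,
              flat = flat, pre_h = pre_h, h = h, drop_mask = drop_mask,
              logits = logits, attention = A)
  if (spec$head_type == "classifier") {
    out$probs <- softmax_rows(logits)
  } else {
    out$risk <- logits[, 1L]
  }
  out
}

# Backward pass: gradient of the loss wrt every parameter, given
# dL/dlogits. Mirrors fusion_forward exactly.
fusion_backward <- function(params, spec, fw, dlogits) {
  nt <- length(spec$tokens)
  d <- spec$d_joint
  n <- fw$n
  g <- list()

  h_used <- fw$h
  g$Wh2 <- crossprod(h_used, dlogits)
  g$bh2 <- colSums(dlogits)
  dh <- dlogits %*% t(params$Wh2)
  if (!is.null(fw$drop_mask)) dh <- dh * fw$drop_mask
  dh <- dh * (fw$pre_h > 0)
  g$Wh1 <- crossprod(fw$flat, dh)
  g$bh1 <- colSums(dh)
  dflat <- dh %*% t(params$Wh1)

  dFw <- lapply(seq_len(nt), function(i) {
    dflat[, ((i - 1) * d + 1):(i * d), drop = FALSE]
  })
  g$rw <- params$rw * 0
  dO <- vector("list", nt)
  for (i in seq_len(nt)) {
    g$rw[i, ] <- colSums(dFw[[i]] * fw$O[[i]])
    dO[[i]] <- sweep(dFw[[i]], 2, params$rw[i, ], "*")
  }

  dV <- lapply(seq_len(nt), function(j) matrix(0, n, d))
  dA <- array(0, c(n, nt, nt))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    dV[[j]] <- dV[[j]] + fw$A[, i, j] * dO[[i]]
    dA[, i, j] <- rowSums(dO[[i]] * fw$V[[j]])
  }
  dS <- array(0, c(n, nt, nt))
  for (i in seq_len(nt)) {
    Ai <- matrix(fw$A[, i, ], n, nt)
    dAi <- matrix(dA[, i, ], n, nt)
    dS[, i, ] <- Ai * (dAi - rowSums(dAi * Ai))
  }
  scale <- sqrt(d)
  dQ <- lapply(seq_len(nt), function(i) matrix(0, n, d))
  dK <- lapply(seq_len(nt), function(j) matrix(0, n, d))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    dQ[[i]] <- dQ[[i]] + dS[, i, j] * fw$K[[j]] / scale
    dK[[j]] <- dK[[j]] + dS[, i, j] * fw$Q[[i]] / scale
  }
  g$Wq <- matrix(0, d, d); g$Wk <- matrix(0, d, d); g$Wv <- matrix(0, d, d)
  dT <- vector("list", nt)
  for (i in seq_len(nt)) {
    g$Wq <- g$Wq + crossprod(fw$tokens[[i]], dQ[[i]])
    g$Wk <- g$Wk + crossprod(fw$tokens[[i]], dK[[i]])
    g$Wv <- g$Wv + crossprod(fw$tokens[[i]], dV[[i]])
    dT[[i]] <- dQ[[i]] %*% t(params$Wq) + dK[[i]] %*% t(params$Wk) +
      dV[[i]] %*% t(params$Wv)
    if (isTRUE(spec$residual)) dT[[i]] <- dT[[i]] + dO[[i]]
  }

  dCenc <- NULL
  for (b in seq_len(nt)) {
    g[[paste0("Wt2_", b)]] <- crossprod(fw$h1[[b]], dT[[b]])
    g[[paste0("bt2_", b)]] <- colSums(dT[[b]])
    dh1 <- dT[[b]] %*% t(params[[paste0("Wt2_", b)]])
    dh1 <- dh1 * (fw$pre1[[b]] > 0)
    g[[paste0("Wt1_", b)]] <- crossprod(fw$branch_inputs[[b]], dh1)
    g[[paste0("bt1_", b)]] <- colSums(dh1)
    dX <- dh1 %*% t(params[[paste0("Wt1_", b)]])
    # Route the slice of dX feeding from the clinical encoder output.
    tok <- spec$tokens[[b]]
    offset <- 0L
    for (mm in tok$inputs) {
      w <- c(G = spec$d_gene, R = spec$d_clin, I = spec$d_img)[[mm]]
      if (mm == "R") {
        sl <- dX[, (offset + 1):(offset + w), drop = FALSE]
        dCenc <- if (is.null(dCenc)) sl else dCenc + sl
      }
      offset <- offset + w
    }
  }
  if (!is.null(dCenc)) {
    cc <- fw$clin_cache
    g$Wc2 <- crossprod(cc$h, dCenc)
    g$bc2 <- colSums(dCenc)
    dhc <- (dCenc %*% t(params$Wc2)) * (cc$h > 0)
    g$Wc1 <- crossprod(fw$inputs$C_raw, dhc)
    g$bc1 <- colSums(dhc)
  }
  g[names(params)]
}

#' Class-imbalance weights by inverse class proportion
#'
#' The weight of class c is `N_total / N_c`, the reciprocal of the class's
#' proportion in the sample, so minority-class samples contribute more to
#' the loss.
#'
#' @param labels Binary vector (1 = positive) or character vector with
#'   values `"positive"`/`"negative"`.
#' @return Named numeric vector `c(negative = ..., positive = ...)`.
#' @export
class_weights <- function(labels) {
  t01 <- .as01(labels)
  n <- length(t01)
  n_pos <- sum(t01 == 1); n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  c(negative = n / n_neg, positive = n / n_pos)
}

.as01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) stop("unexpected labels: ", paste(bad, collapse = ", "))
    as.integer(labels == "positive")
  } else {
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    as.integer(labels)
  }
}

#' Class-weighted binary cross-entropy
#'
#' The mean over samples of `-w_i [t_i log p_i + (1 - t_i) log(1 - p_i)]`,
#' with probabilities clamped to `[1e-12, 1 - 1e-12]` inside the
#' logarithms. With all weights 1 this is exactly the unweighted binary
#' cross-entropy.
#'
#' @param p Predicted positive-class probabilities.
#' @param t Binary labels (or `"positive"`/`"negative"`).
#' @param w Per-sample weights (scalar recycled; default 1).
#' @return The scalar loss.
#' @export
weighted_loss <- function(p, t, w = 1) {
  t01 <- .as01(t)
  if (length(p) != length(t01)) stop("p and t lengths differ")
  w <- rep_len(w, length(p))
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(w * (t01 * log(pc) + (1 - t01) * log(1 - pc)))
}

# Negative Cox partial log-likelihood (Breslow ties) of risk scores, and
# its gradient; normalized by the number of events.
cox_loss <- function(risk, time, event) {
  ne <- sum(event)
  if (ne == 0) stop("no events in batch; Cox loss undefined")
  ord <- order(time, decreasing = TRUE)
  r <- risk[ord]; ev <- event[ord]; tt <- time[ord]
  cs <- cumsum(exp(r))
  grp_end <- stats::ave(seq_along(tt), tt, FUN = max)    # ties contiguous
  grp_start <- stats::ave(seq_along(tt), tt, FUN = min)
  S <- cs[grp_end]                                        # risk-set sums
  loss <- -(sum(r[ev == 1]) - sum(log(S[ev == 1]))) / ne
  inc <- ifelse(ev == 1, 1 / S, 0)
  H <- rev(cumsum(rev(inc)))[grp_start]
  grad_sorted <- (exp(r) * H - ev) / ne
  grad <- numeric(length(risk))
  grad[ord] <- grad_sorted
  list(loss = loss, grad = grad)
}

#' Train the fusion model
#'
#' Full-batch Adam on the class-imbalance weighted cross-entropy
#' (classifier head) or the negative Cox partial likelihood (risk head).
#'
#' @param inputs List with `G`, `C_raw`, `P` matrices as required by the
#'   spec's modalities.
#' @param outcome For the classifier: a vector of labels
#'   (`"positive"`/`"negative"` or 0/1). For the risk head: a list with
#'   `time` and `event`.
#' @param spec A [fusion_spec()].
#' @param epochs Training epochs (default 700).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weighted Use inverse-proportion class weights (default `TRUE`;
#'   classifier head only).
#' @param weight_decay L2 penalty added to the weight gradients (biases and
#'   the reweighting vector are not penalised); essential at small n where
#'   the network would otherwise memorise the training fold.
#' @param lr_schedule `"cosine"` (default) anneals the learning rate to
#'   zero over the configured epochs, freezing the weights smoothly at the
#'   end of training; `"constant"` keeps it fixed.
#' @param seed Seed governing initialisation and any dropout masks.
#' @return A list of class `fusion_model`: `params`, `spec`, `loss_trace`,
#'   and `class_wts` (classifier).
#' @export
train_fusion <- function(inputs, outcome, spec, epochs = 700,
                         learning_rate = 0.001, weighted = TRUE,
                         weight_decay = 0,
                         lr_schedule = c("cosine", "constant"), seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  with_seed(seed, {
    params <- fusion_init(spec)
    opt <- adam_init(params, lr = learning_rate)
    loss_trace <- numeric(epochs)
    class_wts <- NULL
    if (spec$head_type == "classifier") {
      t01 <- .as01(outcome)
      class_wts <- if (weighted) class_weights(t01) else
        c(negative = 1, positive = 1)
      wvec <- unname(class_wts[t01 + 1L])
      n <- length(t01)
    } else {
      time <- outcome$time; event <- outcome$event
    }
    for (ep in seq_len(epochs)) {
      if (lr_schedule == "cosine") {
        opt$lr <- learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      }
      fw <- fusion_forward(params, spec, inputs, training = TRUE)
      if (spec$head_type == "classifier") {
        p <- fw$probs[, 2L]
        loss_trace[ep] <- weighted_loss(p, t01, wvec)
        dl <- (p - t01) * wvec / n
        dlogits <- cbind(-dl, dl)
      } else {
        cl <- cox_loss(fw$risk, time, event)
        loss_trace[ep] <- cl$loss
        dlogits <- matrix(cl$grad, ncol = 1L)
      }
      grads <- fusion_backward(params, spec, fw, dlogits)
      if (weight_decay > 0) {
        for (nm in names(grads)) {
          # query/key projections are exempt: decaying them collapses the
          # attention scores to uniform, removing modality adaptivity
          if (startsWith(nm, "W") && !nm %in% c("Wq", "Wk")) {
            grads[[nm]] <- grads[[nm]] + weight_decay * params[[nm]]
          }
        }
      }
      st <- adam_step(params, grads, opt)
      params <- st$params; opt <- st$state
    }
    structure(list(params = params, spec = spec, loss_trace = loss_trace,
                   class_wts = class_wts),
              class = "fusion_model")
  })
}

#' Predict with a trained fusion model
#' @param object A `fusion_model`.
#' @param inputs Modality input list as in [train_fusion()].
#' @param ... Ignored.
#' @return For a classifier head, the positive-class probabilities; for a
#'   risk head, the risk scores.
#' @export
predict.fusion_model <- function(object, inputs, ...) {
  fw <- fusion_forward(object$params, object$spec, inputs, training = FALSE)
  if (object$spec$head_type == "classifier") fw$probs[, 2L] else fw$risk
}

#' Per-modality attention weights
#'
#' Averages, per patient, the attention mass each modality token receives
#' over all queries; per-patient weights sum to 1. Also reports the cohort
#' mean per token.
#'
#' @param model A `fusion_model` (an untrained parameter set is accepted,
#'   with a warning, and reports initialisation weights).
#' @param inputs Modality input list.
#' @return List with `per_patient` (n x tokens matrix, rows summing to 1)
#'   and `mean` (named numeric vector).
#' @export
extract_modality_attention <- function(model, inputs) {
  if (is.null(model$loss_trace)) {
    warning("model appears untrained; reporting initialisation weights")
  }
  fw <- fusion_forward(model$params, model$spec, inputs, training = FALSE)
  nt <- length(model$spec$tokens)
  received <- sapply(seq_len(nt), function(j) {
    rowMeans(matrix(fw$attention[, , j], fw$n, nt))
  })
  received <- matrix(received, fw$n, nt)
  colnames(received) <- vapply(model$spec$tokens, `[[`, "", "name")
  list(per_patient = received, mean = colMeans(received))
}
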