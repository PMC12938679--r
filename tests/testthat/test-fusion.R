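tiny_spec <- function(...) {
  fusion_spec(d_gene = 3, d_clin_raw = 4, d_clin = 3, d_img = 6,
              d_joint = 5, hidden = 4, clin_hidden = 3, seed = 9, ...)
}

tiny_inputs <- function(n = 8, seed = 1) {
  with_seed(seed, list(G = matrix(rnorm(n * 3), n),
                       C_raw = matrix(rnorm(n * 4), n),
                       P = matrix(rnorm(n * 6), n)))
}

test_that("softmax and attention normalisation hold for random inputs", {
  spec <- tiny_spec()
  params <- fusion_init(spec)
  with_seed(2, {
    for (rep in 1:25) {
      inputs <- list(G = matrix(rnorm(12), 4), C_raw = matrix(rnorm(16), 4),
                     P = matrix(rnorm(24), 4))
      fw <- fusion_forward(params, spec, inputs)
      expect_equal(rowSums(fw$probs), rep(1, 4), tolerance = 1e-6)
      for (i in seq_along(spec$tokens)) {
        expect_equal(rowSums(matrix(fw$attention[, i, ], 4)), rep(1, 4),
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("width mismatches name the offending modality", {
  spec <- tiny_spec()
  params <- fusion_init(spec)
  inputs <- tiny_inputs()
  bad <- inputs; bad$P <- bad$P[, 1:3]
  expect_error(fusion_forward(params, spec, bad), "image embedding")
  bad <- inputs; bad$G <- cbind(bad$G, 0)
  expect_error(fusion_forward(params, spec, bad), "gene features")
  bad <- inputs; bad$C_raw <- NULL
  expect_error(fusion_forward(params, spec, bad), "missing input")
})

test_that("analytic gradients match finite differences on both heads", {
  for (cfg in list(list(tm = "2token", head = "classifier"),
                   list(tm = "3token", head = "risk"))) {
    spec <- tiny_spec(token_mode = cfg$tm, head_type = cfg$head)
    params <- fusion_init(spec)
    # jitter every parameter (including zero biases) so no pre-activation
    # sits exactly on a ReLU kink, where finite differences are undefined
    params <- with_seed(31, lapply(params, function(p)
      p + stats::rnorm(length(p), sd = 0.05)))
    n <- 6
    inputs <- tiny_inputs(n, seed = 3)
    with_seed(4, {
      t01 <- rbinom(n, 1, 0.5)
      w <- runif(n, 0.5, 2)
      time <- rexp(n); event <- c(1, rbinom(n - 1, 1, 0.7))
    })
    lossfun <- function(pp) {
      fw <- fusion_forward(pp, spec, inputs)
      if (cfg$head == "classifier") weighted_loss(fw$probs[, 2], t01, w)
      else radfusion:::cox_loss(fw$risk, time, event)$loss
    }
    fw <- fusion_forward(params, spec, inputs)
    dlogits <- if (cfg$head == "classifier") {
      dl <- (fw$probs[, 2] - t01) * w / n
      cbind(-dl, dl)
    } else {
      matrix(radfusion:::cox_loss(fw$risk, time, event)$grad, ncol = 1)
    }
    grads <- radfusion:::fusion_backward(params, spec, fw, dlogits)
    # spot-check every parameter tensor at a few entries
    with_seed(5, {
      for (nm in names(params)) {
        idx <- sample(seq_along(params[[nm]]),
                      min(4, length(params[[nm]])))
        for (i in idx) {
          eps <- 1e-6
          p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
          p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
          num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
          expect_lt(abs(num - grads[[nm]][i]), 1e-6)
        }
      }
    })
  }
})

test_that("gradient flows to every modality branch (no dead branch)", {
  spec <- tiny_spec()
  params <- fusion_init(spec)
  n <- 10
  inputs <- tiny_inputs(n, seed = 6)
  with_seed(7, t01 <- rbinom(n, 1, 0.5))
  fw <- fusion_forward(params, spec, inputs)
  dl <- (fw$probs[, 2] - t01) / n
  grads <- radfusion:::fusion_backward(params, spec, fw, cbind(-dl, dl))
  norms <- vapply(grads, function(g) sqrt(sum(g^2)), 0)
  # every projection weight, the clinical encoder, attention and head
  # receive nonzero finite gradient
  for (nm in c("Wc1", "Wt1_1", "Wt1_2", "Wq", "Wk", "Wv", "rw", "Wh1")) {
    expect_true(is.finite(norms[[nm]]))
    expect_gt(norms[[nm]], 0)
  }
})

test_that("forward pass is deterministic and dropout is off at evaluation", {
  spec <- tiny_spec(dropout = 0.5)
  params <- fusion_init(spec)
  inputs <- tiny_inputs()
  f1 <- fusion_forward(params, spec, inputs, training = FALSE)
  f2 <- fusion_forward(params, spec, inputs, training = FALSE)
  expect_identical(f1$probs, f2$probs)
  expect_null(f1$drop_mask)
})

test_that("identical tokens receive equal attention at initialisation", {
  # two identical modality tokens score equally under any shared
  # projections, so each query splits its mass 0.5 / 0.5
  spec <- fusion_spec(d_gene = 6, d_clin_raw = 1, d_img = 6, d_joint = 5,
                      hidden = 4, modalities = c("I", "G"),
                      token_mode = "3token", seed = 3)
  params <- fusion_init(spec)
  # make both branches identical so the tokens coincide
  params$Wt1_2 <- params$Wt1_1
  params$bt1_2 <- params$bt1_1
  params$Wt2_2 <- params$Wt2_1
  params$bt2_2 <- params$bt2_1
  with_seed(8, x <- matrix(rnorm(5 * 6), 5))
  fw <- fusion_forward(params, spec, list(G = x, P = x))
  expect_equal(as.vector(fw$attention), rep(0.5, 5 * 4), tolerance = 1e-12)
})

test_that("training reduces the loss and is reproducible under a seed", {
  n <- 40
  with_seed(10, {
    inputs <- list(G = matrix(rnorm(n * 3), n), C_raw = matrix(rnorm(n * 4), n),
                   P = matrix(rnorm(n * 6), n))
    labels <- as.integer(inputs$G[, 1] + rnorm(n, sd = 0.5) > 0)
  })
  spec <- tiny_spec()
  m1 <- train_fusion(inputs, labels, spec, epochs = 60, seed = 4)
  m2 <- train_fusion(inputs, labels, spec, epochs = 60, seed = 4)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$loss_trace[60], m1$loss_trace[1])
  expect_true(all(is.finite(m1$loss_trace)))
})

test_that("risk head emits finite scalars and ranks by planted signal", {
  n <- 60
  with_seed(11, {
    u <- rnorm(n)
    inputs <- list(G = cbind(u, matrix(rnorm(n * 2), n)),
                   C_raw = matrix(rnorm(n * 4), n),
                   P = matrix(rnorm(n * 6), n))
    time <- rexp(n, exp(u))
    event <- rbinom(n, 1, 0.8); event[1] <- 1
  })
  spec <- tiny_spec(head_type = "risk")
  m <- train_fusion(inputs, list(time = time, event = event), spec,
                    epochs = 150, seed = 5)
  r <- predict(m, inputs)
  expect_true(all(is.finite(r)))
  expect_length(r, n)
  # concordance with the planted risk direction on training data
  expect_gt(cor(r, u, method = "spearman"), 0.3)
})

test_that("modality attention weights sum to one and are order-invariant", {
  spec <- tiny_spec()
  params <- fusion_init(spec)
  inputs <- tiny_inputs(12, seed = 13)
  model <- structure(list(params = params, spec = spec,
                          loss_trace = numeric(1)),
                     class = "fusion_model")
  att <- extract_modality_attention(model, inputs)
  expect_equal(rowSums(att$per_patient), rep(1, 12), tolerance = 1e-9)
  perm <- sample(12)
  att2 <- extract_modality_attention(model, lapply(inputs, function(m)
    m[perm, , drop = FALSE]))
  expect_equal(att$mean, att2$mean, tolerance = 1e-12)
  # untrained parameter sets are reported with a warning
  bare <- structure(list(params = params, spec = spec),
                    class = "fusion_model")
  expect_warning(extract_modality_attention(bare, inputs), "untrained")
})

test_that("cox loss matches the oracle partial likelihood and its slope", {
  with_seed(14, {
    n <- 9
    r <- rnorm(n)
    time <- sample(50, n)
    event <- c(1, rbinom(n - 1, 1, 0.6))
  })
  cl <- radfusion:::cox_loss(r, time, event)
  expect_equal(cl$loss, -oracle_cox_pll(1, r, time, event) / sum(event),
               tolerance = 1e-10)
  # finite-difference slope of the loss in each risk coordinate
  for (i in seq_len(n)) {
    eps <- 1e-6
    r1 <- r; r1[i] <- r1[i] + eps
    r2 <- r; r2[i] <- r2[i] - eps
    num <- (radfusion:::cox_loss(r1, time, event)$loss -
              radfusion:::cox_loss(r2, time, event)$loss) / (2 * eps)
    expect_lt(abs(num - cl$grad[i]), 1e-6)
  }
})
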