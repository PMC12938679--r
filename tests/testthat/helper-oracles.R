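# Independent oracle implementations used to validate package routines.
# These are deliberately naive (enumeration / direct formula evaluation)
# and share no code with the implementation paths they check.

# Cox partial log-likelihood (Breslow) evaluated directly from its
# definition, and a grid-search maximizer over beta.
oracle_cox_pll <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      riskset <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[riskset])))
    }
  }
  ll
}

oracle_cox_beta <- function(x, time, event, lo = -8, hi = 8, tol = 1e-6) {
  stats::optimize(function(b) oracle_cox_pll(b, x, time, event),
                  c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# Product-limit estimator computed directly from counts.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, survival = NA_real_)
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Two-sample log-rank statistic by direct O-E / hypergeometric-variance
# evaluation at each distinct event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1L
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Tiny random survival instance without ties, for the Cox grid checks.
random_tiefree_instance <- function(n) {
  list(x = round(stats::rnorm(n), 2),
       time = sample(seq_len(100), n),        # distinct times
       event = {e <- stats::rbinom(n, 1, 0.7); if (sum(e) == 0) e[1] <- 1; e})
}

# A small valid cohort for I/O and fit tests, with controllable size.
make_test_cohort <- function(n = 40, n_genes = 12, d_img = 6, seed = 1) {
  with_seed(seed, {
    expr <- matrix(stats::rnorm(n * n_genes), n,
                   dimnames = list(NULL, paste0("g", seq_len(n_genes))))
    ref <- matrix(stats::rnorm(n * n_genes), n, dimnames = dimnames(expr))
    ref[, 1:4] <- ref[, 1:4] - 2
    u <- stats::rnorm(n)
    days <- round(stats::rexp(n, rate = exp(u) / 1800)) + 1
    event <- stats::rbinom(n, 1, 0.8)
    clin <- data.frame(
      age = round(stats::rnorm(n, 60, 8)),
      clinical_stage = sample(paste("Stage", c("I", "II", "III", "IV")), n,
                              replace = TRUE),
      stringsAsFactors = FALSE)
    cohort(patient_id = paste0("P", seq_len(n)), survival_days = days,
           event = event,
           embedding = matrix(stats::rnorm(n * d_img), n),
           expression = expr, clinical = clin, expression_ref = ref)
  })
}

# Shared small-footprint training configuration for network tests: reduced
# widths and epochs keep each fit to a couple of seconds.
small_control <- function(...) {
  train_control(epochs = 200, ae_widths = c(64, 32), ae_latent = 16,
                ae_epochs = 80, d_joint = 32, hidden = 32,
                weight_decay = 3, ...)
}

# Small generator config matching the study-structure defaults but with a
# desk-scale gene panel and embedding handled at full width only where a
# test needs it.
small_gen <- function(...) {
  generator_config(n_patients = 300, n_genes = 100, ...)
}
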