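---
title: "Multimodal fusion modelling of tumor radiosensitivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion modelling of tumor radiosensitivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radfusion)
```

## The problem

Radiotherapy benefits only part of the patients who receive it. A patient's
*radiosensitivity* — whether their tumor responds favorably — is not
observable before treatment, so it is operationalized retrospectively from
survival: patients surviving more than five years after radiotherapy are
treated as radiosensitive (positive), patients who died within five years
as radioresistant (negative). Patients with under 30 days of follow-up are
removed, since very early deaths are usually unrelated to the tumor's
radiation response. Patients *censored* before the five-year mark can be
assigned to neither class without immortal-time bias; `radfusion` excludes
them by default and offers a sensitivity-analysis flag
(`derive_label(..., censored_policy = "positive")`) that counts them as
survivors instead. The boundary case — death at exactly 1825 days — counts
as "within five years".

Three modalities describe each patient:

* **P**, a slide-level embedding of the whole-slide pathology image
  (768-dimensional by default), produced upstream by a frozen foundation
  encoder and consumed here as a plain numeric vector. The package never
  touches image pixels.
* **z**, a gene-expression profile, reduced by the package to a compact
  radiosensitivity-gene feature vector **G** (9 genes by default).
* **v**, raw clinical variables (age, stage, grade), cleaned and encoded to
  a 6-dimensional clinical representation **C**.

## Gene selection: `G = Cox(Auto(z))`

The genomic branch condenses thousands of genes to a 9-gene feature vector
in three stages:

1. **Differential-expression screen.** A per-gene two-sample Welch *t*
   test between the observed profiles and a treatment-contrast reference
   matrix, with Benjamini–Hochberg control at `alpha_de = 0.05`. Paired
   contrasts are available (`paired = TRUE`). Genes with zero variance in
   both groups get p = 1 rather than NaN. Public expression resources
   rarely contain paired post-radiotherapy profiles, so the contrast is
   deliberately generic: any two-group design fits, and the synthetic
   generator emits the two groups explicitly.
2. **Autoencoder compression.** The DE genes are z-scored per gene (mixed
   dynamic ranges otherwise destabilize the reconstruction loss) and
   compressed by a dense autoencoder: encoder widths 1024 and 512 with
   ReLU activations, a linear 100-unit bottleneck, and a mirror-image
   decoder, trained by full-batch Adam on mean-squared reconstruction
   error (300 epochs, learning rate 0.001 by default). The implementation
   is plain vectorized R with analytic backpropagation; finite-difference
   tests pin the gradients.
3. **Univariate Cox screen and gene attribution.** Each latent is fitted
   against overall survival by univariate Cox proportional-hazards
   regression (Breslow ties, Wald p-values, via the `survival` package);
   latents with p ≤ `alpha_cox = 0.05` are retained. The latents must
   then be traced back to genes. We rank genes by their *loading* on the
   selected latents: the sum over selected latents of
   `|Wald z| * |cor(latent, gene)|`. Input-gradient attribution was
   implemented first and rejected on measurement: for a correlated gene
   block the trained encoder reads the block's shared factor as an
   average, which makes per-gene encoder gradients *smaller* inside the
   block than outside it and inverts the intended ranking (0/9 planted
   genes recovered, versus 9/9 for loading attribution on the same
   fixtures). If no latent passes the screen the pipeline falls back,
   with a warning, to Wald-weighted loadings over all latents; the
   alternative — aborting — made modality-ablation arms crash whenever a
   cohort's genomic branch carried no survival signal.

Both significance thresholds default to 0.05; they are exposed because no
canonical values exist for this pipeline.

## Clinical cleaning and encoding: `C = FC(S(v))`

`clean_clinical()` drops variables missing in more than 20% of patients or
with numerically zero variance after encoding, encodes ordinal stage and
grade variables by severity (Stage I < II < III < IV, T1 < … < T4,
N0 < … < N3, G1 < … < G4; a/b sub-stages sort within their stage), gives
other categoricals level codes, and imputes (median for numeric/ordinal,
mode for categorical). Every drop is logged with its reason. The fitted
schema is applied unchanged to new patients; unseen levels map to a
dedicated "unknown" code 0 with a warning. Cleaning is idempotent.
Disease-site presets (`"hnsc"`, `"brca"`) restrict to the variable sets
conventional for those cohorts. Only the variance criterion implements the
"limited discriminatory power" idea; anything sharper (e.g. univariate
label association) would leak outcome information into preprocessing.

The cleaned table is standardized and mapped to the 6-dimensional
representation **C** by a small dense encoder (hidden width 16). The
encoder has no objective of its own: its weights live inside the fusion
model and train end-to-end with the fusion loss.

## The fusion network

Modalities are projected into a shared latent space as a short *token*
sequence. In the default 2-token layout, token 1 is an MLP of the
concatenated `[G; C]` (gene + clinical, which share scale and biological
granularity) and token 2 is an MLP projection of **P** — this makes the
per-modality attention weights directly readable. A 3-token variant
projects G, C and P separately. Each projection MLP has one ReLU hidden
layer; projected width `d_joint` and hidden width default to 64.

Single-head self-attention runs over the token sequence
(`softmax(QKᵀ/√d)V`), with a residual connection adding each token's own
content back to its attended context. The residual is load-bearing:
without it, attention averages every token's value into every position,
and on complementary-signal cohorts the trimodal model performed *worse*
than its best unimodal arm; with it, the fused model dominates. A
learnable reweighting vector `W` (initialised to ones, i.e. identity) then
scales the attended tokens element-wise, and a dense head on the flattened
sequence emits either two-class softmax probabilities or, in the
survival variant, a scalar risk score.

Whether the attention of the original design operates over feature
positions or modality blocks is ambiguous; both token layouts are
provided, and the 2-token default is the one under which "weight per
modality" is well defined.

### Training

Full-batch Adam, learning rate 0.001, 700 epochs by default. The
classifier minimizes class-weighted binary cross-entropy, each sample
weighted by the reciprocal of its class's proportion
(`w_c = N / N_c`), with probabilities clamped at 1e-12 inside the logs;
with unit weights this is exactly the standard cross-entropy, and the
weighting flag (`weighted`) can turn it off. The risk head minimizes the
negative Cox partial likelihood (Breslow ties) of the batch, normalized
by the number of events.

Two additions stabilize training at cohort sizes of a few hundred, where
a 768-input network otherwise memorizes the training fold outright
(training AUC 1.0, held-out AUC ~0.55 in our development experiments):

* **Weight decay** on all projection and head weights (default 0.01 for
  exploratory fits; the reference evaluation protocol uses 2 with the
  schedule below). Biases, the reweighting vector, and the attention
  query/key projections are exempt — decaying Q/K collapses the attention
  scores to exactly uniform weights and removes the modality adaptivity
  the attention exists to provide.
* **Cosine learning-rate annealing** to zero over the configured epochs,
  so the endpoint of training is a smooth freeze rather than a
  knife-edge; with a constant rate, strong decay produced oscillatory
  shrink-and-recover dynamics whose endpoint was unstable to ±1 in the
  epoch count.

Because total regularization scales with the integral of the learning
rate, shorter schedules need stronger decay; the reference evaluation
configuration (400 epochs, decay 2) was chosen on held-out splits of
development cohorts and is used consistently for every arm of every
comparison.

## Evaluation protocol

`cross_validate()` runs stratified five-fold cross-validation: folds are
assigned round-robin within each class after a seeded shuffle, so each
fold's class ratio is within one patient of the global ratio (plain random
division can produce single-class folds at a 43-negative cohort size).
*All* preprocessing — DE screen, autoencoder, Cox screen, attribution,
clinical schema, standardization — is refitted on each training fold;
held-out patients never influence feature selection. Metrics at the 0.5
threshold (precision, recall, F1, accuracy) plus rank-based AUC are
reported per fold and averaged; the mean ROC curve is vertical averaging
on a 101-point FPR grid. Excluded-label patients never enter training or
testing. `ablation()` reruns the identical protocol with a modality subset,
removing absent modalities from the token sequence rather than zeroing
them; passing a shared fold assignment pairs the arms for lower-variance
comparisons.

`stratify_and_test()` evaluates the survival variant: out-of-fold risk
scores for every patient (folds stratified on the event indicator),
pooled and split at the median — ties at the median go to the low-risk
group — followed by Kaplan–Meier curves per group and the two-sample
log-rank test. Out-of-fold pooling is our reading of evaluation on
"combined cross-validation test sets"; refit-on-all scoring would be
optimistic. Any strictly monotone transform of the scores leaves the
stratification unchanged.

## The synthetic cohort generator

`generate_cohort()` draws a shared latent `s` and per-modality latents
`v_m = ρ·s + √(1−ρ²)·e_m`; the patient's risk `u` is the equal-weight mean
of the active modality latents, rescaled to unit variance so the planted
log hazard ratio is exact. Survival is exponential with hazard
`λ₀·exp(β·u)` under independent exponential censoring; `λ₀` and the
censoring rate are calibrated by deterministic root-finding so the
*expected* positive:negative ratio matches the configured imbalance
(default 3:1; 5.6:1 mirrors a breast-cancer-like cohort) and the expected
censored fraction matches `censoring_rate` (default 0.15). Features:
9 prognostic genes load on the genomic latent inside a 40-gene
differential-expression block; embeddings are isotropic noise plus a
rank-5 structured subspace whose first direction carries the image latent;
ordinal clinical variables are noisy copies of the clinical latent cut at
quartiles, with 3% missingness. At `ρ = 0` the modalities carry
complementary parts of the risk; at `ρ = 1` they are redundant.

Signal-strength defaults were calibrated against the reference ablation
pattern (unimodal AUCs in the 0.6s, trimodal near 0.8): the embedding
loading is 2.0 so the image latent is recoverable from its features, and
the planted log-HR is 1.3, placing the cohort-level discriminability
ceiling near 0.82 and unimodal ceilings near 0.67. With β = 1.0 the
trimodal ceiling is only ~0.75, below the pattern being emulated. The
calibration matches printed reference behavior, not a fitted model of any
real dataset.

What the generator does **not** emulate: gene–gene co-expression beyond
the planted block, realistic embedding geometry of any particular
foundation encoder, non-proportional hazards, informative censoring, or
correlated missingness. Tests passing on these cohorts show the machinery
is correct and well calibrated under its own assumptions; they are not
evidence about any real cohort.

## Numerical choices and degenerate inputs

* Constant Cox covariates: flat partial likelihood, reported as β = 0,
  HR = 1, p = 1 (never an error inside the screen).
* Zero-variance genes in the DE screen: p = 1, not NaN.
* Probability clamping at 1e-12 inside cross-entropy logs.
* Ties: Breslow approximation everywhere in partial likelihoods; rank
  ties in AUC averaged (Mann–Whitney convention).
* Median-split ties go to the low-risk group, deterministically.
* ReLU subgradient at 0 is taken as 0; gradient tests jitter parameters
  off the kink, where central differences are undefined.
* All randomness (initialisation, fold shuffles, dropout masks) flows
  from explicit seeds; fits restore the caller's RNG state.

## Reference evaluation sizes

Tests and the acceptance script evaluate on 300-patient cohorts with a
100-gene panel, autoencoder widths 128/64 with 20 latents (100 epochs),
fusion width 32, 400 training epochs at decay 2. These sizes are the
package's reference configuration for synthetic evaluation; the
full-width defaults (1024/512/100, d_joint 64, 700 epochs) remain the
recommended starting point for real cohorts of a few hundred patients.

## Known limitations

* The DE "before/after radiotherapy" contrast is emulated, not paired
  clinical data; with real paired profiles use `paired = TRUE`.
* The latent→gene attribution rule is a documented choice; the original
  formulation leaves the mapping from screened latents back to named
  genes undefined.
* Single attention head and one hidden layer per MLP; widths are design
  defaults, not tuned to any real dataset.
* The clinical encoder shares the fusion loss; there is no separate
  pretraining objective.
* No multivariable Cox modelling, LASSO signatures, pathway enrichment,
  or time-dependent AUC; the survival variant is evaluated solely by
  median-split stratification.
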