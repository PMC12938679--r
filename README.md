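# radfusion

Multimodal fusion modelling of tumor radiosensitivity in R.

Whether a tumor will respond to radiotherapy is, in practice, read off
survival: patients alive more than five years after radiotherapy are
treated as radiosensitive, patients who died within five years as
radioresistant (follow-up under 30 days is discarded). `radfusion`
predicts this label — and, in a survival variant, a continuous risk
score — by fusing three per-patient modalities:

* a slide-level pathology embedding **P** ∈ ℝ⁷⁶⁸ (produced upstream by a
  frozen foundation encoder; consumed here as a numeric vector),
* a gene-expression profile **z**, reduced to a compact
  radiosensitivity-gene vector **G** ∈ ℝ⁹ by a three-stage pipeline
  `G = Cox(Auto(z))`: differential-expression screen (Welch *t* +
  Benjamini–Hochberg), autoencoder compression (1024–512–100
  bottleneck), univariate Cox screening of the latents (Breslow ties,
  Wald p ≤ 0.05) with loading-based attribution back to genes,
* clinical variables **v**, cleaned (missingness/variance filters,
  severity-ordered ordinal encoding, imputation) and projected to
  **C** ∈ ℝ⁶ by an encoder trained end-to-end with the fusion loss.

The fusion network arranges the modalities as tokens in a shared latent
space — `F_concat = [MLP([G;C]); MLP(P)]` — refines them with single-head
self-attention (`F_att = SelfAttn(F_concat)`, residual connection),
rescales with a learnable element-wise weight vector
(`F_weighted = W ⊙ F_att`), and classifies with a softmax head:
`ŷ = Softmax(MLP(F_weighted))`. Training is full-batch Adam
(lr 0.001, 700 epochs by default, cosine-annealed) under class-weighted
cross-entropy, each sample weighted by the reciprocal of its class's
proportion — the weighted loss
`-(1/N) Σ wᵢ [tᵢ log pᵢ + (1−tᵢ) log(1−pᵢ)]` — to counter the roughly
3:1 to 5.6:1 positive:negative imbalance of radiotherapy cohorts. The
survival variant swaps the head for a scalar risk score trained with the
negative Cox partial likelihood.

Evaluation follows stratified five-fold cross-validation with all
preprocessing refitted per training fold (no leakage), threshold-0.5
metrics plus rank AUC, vertically averaged ROC curves, modality ablation
(I / G / R and combinations, with absent modalities removed from the
token sequence), per-modality attention-weight extraction, and
Kaplan–Meier stratification of pooled out-of-fold risk scores at the
median with a log-rank test.

A seeded synthetic-cohort generator plants all of this structure (latent
patient risk, exponential survival with calibrated imbalance and
censoring, prognostic gene block, low-rank embedding signal, ordinal
clinical covariates, tunable cross-modal redundancy ρ), so every stage is
testable without external data.

## Worked example

```r
library(radfusion)

coh <- generate_cohort(generator_config(n_patients = 300, n_genes = 100,
                                        seed = 1))
print(coh)
#> cohort: 300 patients, 100 genes, 768-dim embeddings, 5 clinical variables
#> labels: 219 positive / 76 negative / 5 excluded

ctrl <- train_control(epochs = 400, ae_widths = c(128, 64), ae_latent = 20,
                      ae_epochs = 100, d_joint = 32, hidden = 32,
                      weight_decay = 2)
fit <- radfusion(coh, control = ctrl, seed = 1)
summary(fit)
#> radfusion classifier model (modalities: I, G, R; n = 295)
#> selected genes: gene_003, gene_004, gene_008, gene_002, gene_009, ...
#> clinical variables: age, clinical_stage, tumor_grade, path_t_stage, path_n_stage
#> class weights: negative 3.882, positive 1.347
#> mean attention per modality token:
#> gene+clinical         image
#>        0.3872        0.6128

cv <- cross_validate(coh, control = ctrl, seed = 1)
print(cv)
#> 5-fold cross-validation, modalities {I, G, R}
#> mean metrics:
#> precision    recall        f1  accuracy       auc
#>    0.8736    0.8129    0.8416    0.7730    0.8247

km <- stratify_and_test(coh, control = ctrl, seed = 1)
print(km)
#> median risk split: 149 high-risk / 150 low-risk
#> log-rank test: chi-square = 33.1027 (1 df), p = 8.74e-09
```

The cross-validated AUC (0.82 here) measures out-of-fold discrimination
of five-year survivors from non-survivors; the class weights show the
inverse-proportion loss weighting actually applied; the attention row is
the mean attention mass each modality token receives; and the log-rank
p-value tests whether the median split of pooled out-of-fold risk scores
separates the two groups' survival curves (it does, decisively, on this
planted-signal cohort).

A thin command-line wrapper over the same functions ships in
`inst/cli/radfusion.R`:

```sh
Rscript inst/cli/radfusion.R simulate --out cohort_dir --seed 1
Rscript inst/cli/radfusion.R train --cohort cohort_dir --out run1
Rscript inst/cli/radfusion.R ablate --cohort cohort_dir --modalities I,G
Rscript inst/cli/radfusion.R survival --cohort cohort_dir --out run1
```

## Package layout

* `R/cohort.R` — cohort container, labeling rules, file I/O
* `R/synthetic.R` — the cohort generator
* `R/gene_selection.R` — DE screen, autoencoder, Cox screen, attribution
* `R/clinical.R` — cleaning, ordinal encoding, clinical encoder
* `R/fusion.R` — the attention fusion network and trainers
* `R/fit.R`, `R/crossval.R` — the `radfusion()` model interface,
  cross-validation, ablation
* `R/survival_km.R` — Kaplan–Meier, log-rank, median stratification
* `R/pipeline.R` — end-to-end pipeline with manifests
* `vignettes/radfusion-methods.Rmd` — model, assumptions, design choices
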