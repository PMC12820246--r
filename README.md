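# neurofuse

Attention-based multimodal fusion for classifying Alzheimer's disease (AD),
Parkinson's disease (PD), and healthy controls (HC) from three data
modalities — structural MRI volumes, multichannel EEG recordings, and SNP
genotype vectors — with Monte-Carlo-dropout uncertainty estimates on every
prediction.

The package is aimed at researchers studying multimodal fusion mechanics:
it ships a synthetic tri-modal cohort generator that plants known,
class-dependent signal in every modality (regional intensity loss in
volumes, EEG band-power shifts, class-enriched risk-allele frequencies,
partial-modality patterns, multiplicative scanner bias), so the whole
pipeline — preprocessing, encoders, fusion, uncertainty, evaluation,
ablation, saliency — can be validated against ground truth without access
to clinical data.

## The model

Each modality is encoded into tokens of a shared fusion dimension:

* **SNP**: one-hot genotypes (AA/AG/GG) → PCA (95% explained variance) →
  min–max scaling → dense embedding `Z_S = W_S S' + b_S` → token chunks →
  bidirectional LSTM;
* **MRI**: simplified polynomial bias-field correction → min–max
  normalization → 3-D patches → shared 3-D CNN (one token per patch);
* **EEG**: 0.5–40 Hz zero-phase bandpass → Welch band powers
  (delta/theta/alpha/beta per channel, log, z-scored) → 1-D CNN over the
  channel axis.

Fusion is single-head scaled dot-product attention: per-modality
self-attention `A = softmax(Q K' / √d_k)`, `O = A V`, plus directed
cross-modality attention `C_SM`, `C_SE`, `C_ME`, combined per modality as

    F_S = O_S + C_SM + C_SE
    F_M = O_M + C_SM + C_ME
    F_E = O_E + C_SE + C_ME

(attended outputs mean-pooled over tokens and projected to the fusion
dimension first). The concatenation `[F_S‖F_M‖F_E]` passes through a dense
layer, dropout, and a LayerNorm → GLU → residual refinement to three class
logits with a temperature-calibrated softmax.

Uncertainty comes from 30 stochastic dropout passes: posterior mean
`μ = mean(y_t)`, epistemic variance `σ² = mean((y_t − μ)²)` (class-mean
summary), aleatoric term `mean_t Σ_c y_tc(1 − y_tc)`, and
`U_final = σ² + U_aleatoric`. Training minimizes

    L_final = L_CE + U_final + λ‖W‖₂² + α|W| + D_KL + L_focal

with Adam (weight decay 1e-5, gradient-norm clipping at 1.0) on a staged
schedule (`full_schedule()` is the 10-stage table: lr 0.001→0.00001, batch
32→16, dropout 0.5→0.2, epochs 10→50).

All network forward/backward passes are hand-written base R matrix algebra
(no deep-learning framework is used) and are verified against numerical
differentiation in the test suite.

## Worked example

```r
library(neurofuse)

spec <- cohort_spec(n_subjects = 120, volume_shape = c(16, 16, 16),
                    n_timesteps = 1000, n_snps = 60, n_risk_loci = 12,
                    frac_complete = 0.8, seed = 42)
cohort <- generate_cohort(spec)
cohort
#> <nf_cohort> 120 subjects (AD=40, PD=40, HC=40); 96 complete tri-modal

fit <- fit_evaluate(cohort,
                    nf_config(d_k = 16, pca_cap = 12, head_dropout = 0.3),
                    schedule = desk_schedule(epochs = c(12, 6)), seed = 42)
fit$metrics
#> accuracy 1.000 | macro F1 1.000 | macro AUROC 1.000
```

The default planted effects (20% regional intensity loss, +3 dB band
shifts, 0.45 vs 0.15 risk-allele frequencies) are strong enough that the
held-out test subjects here are all classified correctly.  A harder task —
the cross-modal interaction cohort, where AD vs PD is decidable only by
combining SNP and EEG evidence — shows the uncertainty machinery at work:

```r
co <- generate_cohort(interaction_cohort_spec(n_subjects = 210, seed = 7))
ss <- interaction_study_settings()
fit <- fit_evaluate(co, ss$config, schedule = ss$schedule, seed = 7)
fit$metrics
#> accuracy 0.935 | macro F1 0.933 | macro AUROC 1.000
#>   sensitivity specificity precision   npv    f1 auroc auprc
#> 1         0.8       1.000     1.000 0.913 0.889     1     1
#> 2         1.0       0.905     0.833 1.000 0.909     1     1
#> 3         1.0       1.000     1.000 1.000 1.000     1     1

uncertainty_report(fit$uncertainty$U_final, correct = fit$correct)
#>  component     group  n        mean       median          iqr
#>    U_final   correct 29 0.008500799 1.846720e-27 1.610305e-11
#>    U_final incorrect  2 0.122225399 1.222254e-01 8.072473e-02
#> one-sided Mann-Whitney p (incorrect > correct): 0.02016
```

93.5% of the 31 held-out subjects are classified correctly, and the two
misclassified subjects carry roughly 14 times the mean total predictive
uncertainty of the correct ones.  (Output from this exact script; the last
digits can vary with the platform's BLAS.)

Saliency maps for a trained model:

```r
inputs <- build_model_inputs(cohort, fit$fitstats)
sal <- volume_saliency(fit$model, inputs, subject = fit$split$test[1],
                       target_class = "AD")   # 3-D array in [0, 1]
eeg <- eeg_saliency(fit$model, inputs, fit$split$test[1], "AD")  # 4 x channels
```

A thin command-line wrapper lives at `inst/cli/neurofuse-cli.R`
(`simulate`, `show-config`, `describe-model`, `fit`, `ablate`, `explain`).

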