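# ebdl — band-dependent learning for radar time-frequency classification

Radar returns from human motion are usually classified from their
spectrograms (time-frequency representations, TFRs). Those TFRs are
*band dependent*: the shape of a class-relevant pattern changes with the
frequency band it occupies, and its power scale does too — a torso
reflects orders of magnitude more power than a foot, breathing moves the
chest far more than a heartbeat. Both properties fight the priors of a
plain convolutional classifier: translation invariance along frequency is
wrong, and feature learning is biased toward high-power bands.

`ebdl` implements an enhanced band-dependent learning model for this
setting, end to end:

* **Adaptive sub-band filtering** — M trainable filters, each a
  generalized-Gaussian scaling profile over the normalized frequency axis,

  `g(f; μ, σ, β) = exp(−(|f − μ| / σ)^β)`,

  with trainable location μ and scale σ (β fixed, even, default 8). Each
  filter turns the input TFR into one *sub-view* `x·bᵢ`.
* **Shared representation learning** — one encoder (backbone + projection
  head) embeds every sub-view as a unit vector `z_i ∈ R^L` on a common
  hypersphere.
* **Sub-view contrastive loss (SCLoss)** — trainable class proxies
  `p_{i,c}` per sub-view and class; each embedding is pulled toward its
  same-view/same-class proxy, pushed from same-view/other-class proxies,
  and its similarity to *other-view* same-class proxies is capped at zero
  through a ReLU, so distinct sub-views learn distinct features:

  `−log [ e^{p̃·zᵢ} / (e^{p̃·zᵢ} + Σ_{A(i)} e^{p·zᵢ} + Σ_{B(i)} e^{ReLU(p·zᵢ)}) ]`

  Prediction takes the class of the most similar proxy across all
  sub-views (cosine similarity, each view compared to its own proxies).

The package also provides the full preprocessing pipeline (segmentation,
Butterworth band-pass, two-sided STFT, log scaling, standardization,
magnitude/phase composition, mix augmentation for class imbalance),
evaluation with balanced accuracy and per-class precision/sensitivity,
validation-based filter-count selection, leave-one-subject-out splitting,
and synthetic generators of band-dependent tasks so everything runs at
desk scale with no external data. Training (including the convolutional
encoder's backward pass) is implemented natively in R.

## Worked example

Generate a two-class band task whose discriminative ridges sit 20 dB
below a shared nuisance component, train a 3-filter model, and evaluate:

```r
library(ebdl)

cfg <- synthetic_config(n_classes = 2, samples_per_class = 100,
                        tfr_shape = c(32, 64),
                        class_bands = list(c(0.35, 0.3), c(0.7, 0.25)),
                        power_ratio_db = 20, noise_sd = 0.05, seed = 1)
samples <- gen_band_task(cfg)
split <- split_dataset(samples, c(7, 1.5, 1.5), seed = 1)

fit <- ebdl(split$train, val = split$validation, n_filters = 3,
            epochs = 10, batch_size = 16, lr_encoder = 3e-3,
            lr_proxies = 1e-2, lr_filters = 0.05, seed = 1024,
            stop_at_val_acc = 1)
fit
#> Band-dependent learning model
#>   loss: scloss   classes: 1, 2
#>   input: 32 x 64 TFR   encoder: tiny_cnn (L = 32)
#>   3 sub-band filters (beta = 8):
#>     mu =  -0.368   sigma =   0.984
#>     mu =   0.228   sigma =   0.974
#>     mu =   0.540   sigma =   1.005
#>   trained 10 epoch(s); best checkpoint at epoch 10

evaluate(fit, split$test)
#> <ebdl_eval>  accuracy 1.000   balanced accuracy 1.000
#>  class precision sensitivity
#>      1         1           1
#>      2         1           1
```

The printed filters are the learned `(μ, σ)` pairs: starting from the
uniform initialization (−0.5, 0, 0.5 with σ = 1), the centers have moved
toward the two planted class bands (0.35 and 0.7) while the test set is
classified perfectly despite the 100× stronger nuisance band. `coef(fit)`
returns the same parameters as a matrix, `plot(fit)` draws the filter
profiles, and `predict(fit, newdata)` classifies new samples.

Raw-signal workflows start from `radar_segment()` and
`preprocess_signal()` with `vital_recipe()` or `gait_recipe()`; a thin
command-line wrapper over the same functions is installed at
`inst/cli/ebdl.R` (subcommands `synth`, `preprocess`, `train`, `eval`).

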