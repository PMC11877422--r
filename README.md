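# longipred

Individualised prediction of longitudinal change in volumetric brain
images, for imaging researchers who want to know whether a "follow-up scan
predictor" has learned anything beyond copying its input.

Baseline and follow-up scans of the same person are so similar that naive
prediction benchmarks are dominated by two artefacts: a model can score a
high spatial correlation by **copying** (or copying and denoising) the
baseline, and the temporal difference `B − A` correlates with the baseline
even when no true change exists, because both contain the same baseline
noise. `longipred` provides the statistical framework that controls for
both, plus the predictive model and evaluation machinery around it:

* **Closed-form references.** Under the generative model
  `A = A0 + E_A`, `B = A0 + Δ + E_B`, `Δ = W·A0 + f(A0)`
  (unit-variance signal, i.i.d. Gaussian noise of variance σ² at both time
  points), the no-change null correlation is
  `r(B−A, A) = −1/√(2 + 2/σ²)` and the baseline/follow-up correlation with
  no change equals the data reproducibility `1/(1+σ²)`. General closed
  forms with change present are provided and verified against Monte-Carlo
  simulation in the test suite.
* **Residualisation.** Per-subject scalar regression removes the dominant
  population-average pattern (`ResA`, `ResB`), and the *residual temporal
  difference* `ResB\ResA` — follow-up with the baseline residual regressed
  out — is exactly uncorrelated with the baseline, giving a change metric
  with a zero null.
* **Change-vs-denoising diagnostic.** Feed `ResA` and `ResB` through the
  same model and compare `r(g(ResA), ResB)` with `r(g(ResB), ResA)`: a
  pure denoiser is symmetric, a genuine change predictor is not.
* **A 3D U-Net image-to-image regressor** with stacked multimodal input
  channels, learned positive modality weights, and an
  uncertainty-weighted voxel-wise loss
  `L = Σ_i [ l_i/(2σ_i²) + log(σ_i + 1) ]` with learnable per-voxel scales
  σ_i. The convolution engine (forward and analytic backward) is
  implemented in vectorised R and finite-difference checked in the tests.
* **Explanation.** Weighted saliency maps: the top 5% of predicted voxels
  by absolute value, summing the absolute input-derivative map of each.
* **Evaluation.** Copy-baseline comparisons with percent improvement,
  fingerprint identification rates, and phenotype prediction from change
  maps via principal components + elastic net (`glmnet`).
* **Synthetic cohorts with known ground truth** so all of the above is
  testable without restricted imaging data: smooth unit-variance signals,
  configurable linear/nonlinear change, seeded per-subject substreams, and
  planted phenotype associations.

## Worked example

Generate a synthetic cohort whose true change is a 30% shrinkage of the
baseline pattern (`Δ = −0.3·A0`, σ = 1), residualise it, and compare the
observed change correlation with the closed-form references:

```r
library(longipred)

params <- generative_params(sigma = 1, w_spec = w_scalar(-0.3))
cohort <- generate_cohort(n_subjects = 48, params, shape = 16, seed = 42)
res    <- residualise_cohort(cohort)

null_change_correlation(1)
#> [1] -0.5

r_diff <- mean(sapply(res, function(r)
  masked_correlation(with_mask_values(r$res_b,
    mask_values(r$res_b) - mask_values(r$res_a)), r$res_a)))
round(r_diff, 3)
#> [1] -0.637

expected_change_correlation(params, cov_wa0_a0 = -0.3, var_wa0 = 0.09)
#> [1] -0.636

change_existence_test(observed_r_ab = 0.40, reproducibility = 0.50,
                      observed_r_diff_a = r_diff, sigma = 1)
#> <change_existence_verdict>
#>   r(B,A) vs reproducibility: gap -0.1000 (flag: TRUE)
#>   r(B-A,A) vs null -0.5000:    gap -0.1368 (flag: TRUE)
#>   change evidence: TRUE
```

Reading the numbers: even with **no** change, the temporal difference
would correlate −0.5 with the baseline at this noise level — that is the
null, not evidence of change. The observed −0.637 sits below the null and
matches the closed form for a 30% shrinkage (−0.636) to three decimals;
both gaps flag genuine change. Training the U-Net on the residualised
pairs, running the change-vs-denoising diagnostic and explaining the
predictions then looks like:

```r
ds    <- prepare_training_data(res, target_mode = "followup")
model <- build_model(unet_config(input_shape = c(16, 16, 16), n_levels = 2,
                                 base_channels = 8),
                     seed = 1, mask = attr(ds, "mask"))
model <- train_model(model, ds,
                     train_config(learning_rate = 0.01, batch_size = 8,
                                  epochs = 20, seed = 2),
                     pop_mean = cohort$pop_mean)
denoising_diagnostic(model, res)
explanation_map(model, res[[1]]$res_a, k_fraction = 0.05)
```

(Defaults in `train_config()` follow the full-scale recipe — learning rate
0.001, batch 16, 40 epochs; the values above are the small-cohort
configuration discussed in the vignette.) A command-line surface wrapping
the same functions (`simulate`, `residualise`, `train`, `predict`,
`diagnose`, `explain`, `evaluate`, `nidp`) is installed at
`system.file("cli", "longipred", package = "longipred")`.

See `vignettes/longitudinal-change-prediction.Rmd` for the model,
assumptions, parameter choices and limitations.

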