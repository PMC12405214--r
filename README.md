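# radfusion

Classification of infected versus non-infected cerebrospinal-fluid (CSF)
related regions on 2D MRI slices, for researchers studying noninvasive
imaging correlates of central nervous system infection. Lumbar puncture —
the diagnostic gold standard — is invasive and slow; infection alters CSF
composition, and with it the texture of CSF-filled spaces on T2-weighted
images (the ventricular lumen, and the perivascular spaces of the
sub-lentiform nucleus parenchyma). Those alterations are too subtle for
visual reading, which is exactly the regime where quantitative texture
analysis and learned spatial features help.

The package implements the full pipeline:

* **Radiomics.** A 378-feature vector per ROI: 18 first-order + 9 2D-shape
  + 75 texture features (GLCM 24, GLSZM 16, GLRLM 16, NGTDM 5, GLDM 14)
  from the original image, plus 17 first-order + 75 texture features from
  each of three Laplacian-of-Gaussian responses (fine/medium/coarse,
  in-plane kernels 3/5/7 px): 102 + 3 × 92 = 378. Texture families follow
  IBSI-style definitions (distance 1, four in-plane directions averaged for
  GLCM/GLRLM, 8-connected zones/neighbourhoods, GLDM α = 0) on a 32-level
  equal-width discretization of the in-mask intensities.
* **Selection.** Per outer fold, a univariate ANOVA F score ranks the 378
  features on the training+validation patients only, the top k = 50 are
  kept (ties by catalog order), and they are z-scored with training-only
  statistics. Held-out patient ids are threaded through the calls and any
  leakage aborts the run.
* **Fusion network.** A dual-branch classifier: the backbone feature map
  (7×7×1920 for the DenseNet-201-style backbone at 224×224) feeds four
  parallel 3×3 atrous convolutions with dilation rates 1/6/12/18 (512
  filters each, batch-norm + ReLU) plus a global-context path
  (1×1×1920 pooled → 1×1 conv to 512 → upsampled to 7×7), concatenated to
  7×7×2560 and compressed to 512 channels; the 50 selected radiomics
  features pass Dense(128) → Dense(512) with dropout, are reshaped to
  1×1×512 and upsampled to 7×7×512; both branches concatenate to 7×7×1024,
  then global pooling → Dense(256) + dropout → softmax. The underlying
  layers (im2col convolutions on BLAS, batch-norm, pooling, dense, dropout,
  Adam) are implemented in the package with explicit forward and backward
  passes, gradient-checked in the test suite.
* **Protocol.** Patient-grouped stratified 5-fold nested cross-validation
  (3 inner folds), two-phase training (lr 1e-4 with plateau halving to a
  1e-7 floor, early stopping patience 10, best-weights restore; then 70% of
  layers frozen, lr 1e-5, patience 5), rotation/zoom/translation/flip
  augmentation, per-fold metrics aggregated as mean ± sd with vertically
  averaged ROC, strict patient-wise accuracy (an infected patient is
  correct if *either* ROI is flagged, a control only if *neither* is), and
  left/right discordance rates.
* **Phantom cohort.** Since no clinical data ship with the package, a
  synthetic generator produces balanced two-class cohorts of 2D slices with
  bilateral elliptical ROIs whose mean intensity and noise correlation
  length differ by class — class signal expressed precisely in the
  statistics the feature set measures, so every stage is testable.

## Worked example

```r
library(radfusion)

params <- phantom_params(n_per_class = 20, class_contrast = 0.5, seed = 101)
cohort <- generate_cohort(params)    # 40 patients x 4 ROIs
fit <- run_nested_cv(cohort, region = "sublentiform", model_kind = "fusion",
                     config = train_config_desk(seed = 101))
fit
#> <nested_cv> fusion model, sublentiform region, 5 folds
#> <fold_aggregate>
#>   accuracy   96.25 +/-  8.39 %
#>   precision 100.00 +/-  0.00 %
#>   recall     92.50 +/- 16.77 %
#>   f1         95.38 +/- 10.32 %
#>   AUC        1.000 +/- 0.000
#>   discordance 7.5 +/- 16.8 %
```

Per-fold and aggregate results are tibbles (`tidy()` / `glance()`), and the
selection-frequency table shows which features were chosen in every fold:

```r
tidy(fit)
#> # A tibble: 5 × 6
#>   fold_id accuracy precision recall    f1   auc
#>     <int>    <dbl>     <dbl>  <dbl> <dbl> <dbl>
#> 1       1    100         100  100   100       1
#> 2       2    100         100  100   100       1
#> 3       3    100         100  100   100       1
#> 4       4    100         100  100   100       1
#> 5       5     81.2       100   62.5  76.9     1

head(fit$frequency, 5)
#> # A tibble: 5 × 4
#>   feature                          source   family     frequency
#>   <chr>                            <chr>    <chr>          <int>
#> 1 original_firstorder_Minimum      original firstorder         5
#> 2 original_firstorder_Percentile10 original firstorder         5
#> 3 original_firstorder_Percentile90 original firstorder         5
#> 4 original_firstorder_Maximum      original firstorder         5
#> 5 original_firstorder_Mean         original firstorder         5
```

Here the phantom's class contrast is strong (0.5 intensity shift), so the
nested CV recovers the classes almost perfectly at ROI level (96.25% mean
test accuracy across folds) and intensity-location features are selected in
all five folds — the expected behaviour, since the phantom expresses its
class signal in exactly those statistics. `autoplot(fit)` draws the mean
ROC with its ±1 sd band, `plot_patient_accuracy(fit)` the strict
patient-wise accuracies per class.

This run uses the reduced-scale configuration (`fusion_config_tiny()`,
32×32 inputs, a 3-stage backbone) and the desk training schedule; the
full-scale DenseNet-201-style fusion model is available through
`fusion_config()` and is used for architecture-geometry verification:

```r
m <- build_fusion_model(fusion_config(), seed = 1)
inspect_shapes(m)   # backbone 7x7x1920, ASPP paths 7x7x512, concat 7x7x2560,
                    # radiomics branch 7x7x512, fused map 7x7x1024
```

A command-line front end over the same functions is in
`inst/cli/radfusion.R` (`simulate`, `extract`, `select`, `nested-cv`
subcommands).

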