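---
title: "Methods: radiomics-deep fusion for CSF signal classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics-deep fusion for CSF signal classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Central nervous system infections are usually confirmed by lumbar puncture,
an invasive procedure with contraindications and slow laboratory turnaround.
Infection changes the composition of cerebrospinal fluid (CSF), and those
changes can subtly alter the T2-weighted MRI signal of CSF-filled spaces —
the ventricular lumen and the perivascular spaces of the sub-lentiform
nucleus parenchyma. The texture of those regions is too subtle for visual
reading, which motivates a quantitative pipeline: handcrafted radiomics
features capture first-order and texture statistics of the segmented region,
a convolutional branch captures spatial patterns of a standardized patch,
and the two are fused into a single classifier.

`radfusion` implements this pipeline end to end for 2D slices: each patient
contributes a left and a right ROI per region (segmentation masks are
*inputs*; the package does not segment), and classification is evaluated
patient-wise with a clinically asymmetric rule.

## The phantom cohort

No clinical images ship with the package, so `generate_cohort()` synthesizes
a cohort with exactly the structural properties the pipeline assumes: a
balanced two-class set of patients (default 52 per class), each with
2 regions x 2 hemispheres = 4 elliptical ROIs on a 128 x 128 slice. Class
signal is expressed in precisely the statistics the feature set measures:

* `class_contrast` (default 0.15 on the [0, 1] intensity scale) shifts the
  mean intensity of infected ROIs — detectable by first-order features;
* `class_texture_scale` (default 2.5 px, vs 1 px for controls) sets the
  correlation length of a smoothed Gaussian noise field inside the ROI —
  detectable by texture matrices and LoG-filtered statistics;
* `noise_sd` (default 0.05) is the marginal amplitude of that field.

The texture model is a correlated Gaussian random field (white noise
smoothed with a Gaussian of class-dependent width, renormalized to unit
marginal variance) over a darker parenchyma-like background; ROIs are
randomly oriented ellipses so 2D shape features are nondegenerate. One
master seed expands into one substream per patient (`seed + patient index`),
so enlarging a cohort never perturbs existing patients, and identical
parameters reproduce bit-identical cohorts.

The phantom does *not* emulate CSF flow artifacts, scanner noise spectra,
partial-volume effects, anatomy, or 3D structure. A passing end-to-end test
on the phantom demonstrates that the pipeline recovers class structure that
is expressible in its own feature families — not that it would perform
comparably on clinical data. Because no quantitative effect size for
infected-vs-normal CSF signal is established, the contrast defaults are
tunable study conditions rather than calibrated values.

## Preprocessing

Radiomics uses the original image plus three Laplacian-of-Gaussian (LoG)
responses named fine / medium / coarse with in-plane kernel sizes 3 / 5 / 7
pixels. The analysis is strictly 2D, so the kernel triplets are interpreted
in-plane; default sigmas 0.5 / 1.0 / 1.5 px are chosen so the ~3-sigma
Gaussian support matches those widths, and they are exposed in
`log_scales()`. An alternative millimetre naming of the same scales exists
in clinical practice; only pixel sigmas are computational here because the
phantom's pixel spacing is arbitrary. The LoG is implemented as a
normalized truncated Gaussian followed by the 5-point discrete Laplacian,
both with replicate borders — this makes the response to a constant image
exactly zero and keeps the operation linear.

The network input is a 32 x 32 crop centred on the mask centroid
(edge-replicated at borders), resized with a separable Keys bicubic kernel
(a = -0.5, pixel-centre aligned, edge-clamped) to the configured input
size, linearly rescaled to [0, 1] per patch, and replicated to 3 channels.
Backbones are trained from scratch, so no pretraining-specific
normalization applies. `dice_coefficient()` is provided as a utility for
mask-agreement reporting.

## The 378-feature catalog

Features follow IBSI-style definitions in seven families. The original
image yields 18 first-order + 9 shape (2D) + 24 GLCM + 16 GLSZM + 16 GLRLM
+ 5 NGTDM + 14 GLDM = 102 features; each LoG image yields 92 (17
first-order — Total Energy is defined for original intensities only — plus
the same texture families), giving 102 + 3 x 92 = 378. The published
per-family table this reproduces contains one internally inconsistent row
(its original-image first-order count does not match its own subtotal);
assigning 18 first-order features to the original image and 17 to each LoG
image is the unique resolution consistent with all printed subtotals, and
the catalog (`feature_catalog()`) records the assignment explicitly.

Numerical conventions, all chosen where the underlying study is silent:

* Discretization: 32 equal-width bins over the in-mask intensity range
  (fixed bin *count*, because LoG responses have signed, data-dependent
  ranges); constant ROIs map to level 1. Texture features are therefore
  invariant to constant intensity shifts.
* GLCM/GLRLM: distance 1, four in-plane directions (0/45/90/135 degrees),
  symmetric GLCM, feature values averaged over directions.
* GLSZM: 8-connected zones. NGTDM: 8-neighbourhood, distance 1. GLDM:
  distance 1, similarity threshold alpha = 0, dependence size counting the
  centre pixel.
* Shape: largest 8-connected component; mesh area and perimeter from a
  marching-squares contour with vertices at pixel-edge midpoints (diagonal
  ambiguity resolved as separate corners). The raw midpoint polygon
  overestimates curved perimeters by several percent, so the length (not
  the area) is measured after two Chaikin corner-cutting passes; a
  radius-20 digital disk then yields sphericity ~0.95. Axis lengths come
  from the population covariance of pixel-centre coordinates
  (`4 * sqrt(eigenvalue)`); the maximum diameter is the largest pairwise
  distance between boundary pixel centres.
* First-order percentiles use the standard linear-interpolation quantile
  (type 7); variance/skewness/kurtosis are population moments and kurtosis
  is not excess-corrected.

Every texture matrix is validated in the test suite against independent
brute-force enumerations on random small ROIs.

## Feature selection

Ranking is a univariate one-way ANOVA F score — the canonical deterministic
filter for continuous features with a binary label. Constant features score
0; perfect separators (zero within-class variance) receive a large finite
sentinel (1e12) so the ordering stays total. The top 50 features are kept
per outer fold, ties broken by catalog order. Selection uses the outer
fold's training+validation samples only — patient ids are threaded through
the call and `rank_features()` aborts if a held-out patient reaches the
ranking. Selected features are z-scored with statistics from the *training*
patients only (not the early-stopping validation set) before entering the
network; unscaled radiomics magnitudes (e.g. Energy) would destabilize the
fully connected branch.

## Architecture

The base classifier is a backbone feature extractor, global average
pooling, a 256-unit fully connected layer with dropout 0.3, and a softmax
over two classes. The fusion classifier processes the backbone feature map
(1920 channels on a 7 x 7 grid for the DenseNet-201-style backbone at
224 x 224) through five parallel paths: four 3 x 3 atrous convolutions with
dilation rates 1/6/12/18 (512 filters, batch-norm + ReLU, "same" padding so
the 7 x 7 grid is preserved at all rates, although dilation 18 on a 7 x 7
grid effectively degenerates toward a 1 x 1 support — implemented as
specified regardless), plus a global-context path: global average pooling
(1 x 1 x 1920), a 1 x 1 projection to 512 channels with ReLU, and
upsampling back to 7 x 7. Upsampling from a single cell is constant, so it
is implemented as broadcast replication (bilinear interpolation from one
sample is the same constant). The five 7 x 7 x 512 maps concatenate to
7 x 7 x 2560 and are compressed by a 1 x 1 convolution to 512 channels
(with batch-norm + ReLU). The radiomics branch maps the 50 selected
features through Dense(128) and Dense(512) (ReLU + dropout 0.3 each — the
head rate is reused where the branch rate is unspecified), reshapes to
1 x 1 x 512 and broadcasts to 7 x 7 x 512. Channel concatenation gives the
7 x 7 x 1024 fused map, then global average pooling, Dense(256) with
dropout, and softmax.

The engine behind these models is a self-contained numerical core:
im2col-based convolutions (arbitrary stride/dilation, zero "same" padding)
running on BLAS matrix products, spatial batch normalization, max/average
pooling, dense layers, inverted dropout, channel concatenation and
broadcast upsampling — each with an explicit backward pass, verified
against finite differences in the test suite. The DenseNet-201-style
backbone reproduces the reference topology (growth 32, blocks 6/12/48/32,
bottleneck 4x, compression 0.5, final 1920 channels); the
MobileNetV3-Large-style backbone is a plain-convolution simplification
that preserves the stage schedule and the 960-channel feature map but not
the inverted-residual internals. A `tiny` backbone (32 x 32 input, three
stride-2 stages, 64 channels on a 4 x 4 grid) scales the identical topology
down for desk-scale experiments; width parameters are all configurable
through `fusion_config()`.

The backbone "feature map" is the last convolutional stage output before
any classification head — fixed unambiguously by the 1920-channel / 7 x 7
figures for the densenet-style backbone and applied to the others by the
same rule.

## Training protocol

Optimization is Adam. Phase 1 trains all layers at learning rate 1e-4 with
plateau-based halving (factor 0.5, floor 1e-7, patience 5 epochs — the
plateau patience is unspecified upstream and exposed in `train_config()`),
up to 200 epochs with early stopping after 10 stalled epochs and
best-validation weights restored. Phase 2 freezes the first 70% of the
layer inventory and fine-tunes at 1e-5 for up to 20 epochs, patience 5.
"Layers" for the 70% rule means atomic layer objects (convolutions,
batch-norms, activations, pooling, dense) in forward order — composite
DenseNet units count through their inner layers; the inventory is exposed
by `layer_inventory()` so the rule is auditable. Early stopping monitors
validation loss (the monitored quantity is unstated upstream; loss is the
conventional choice). Frozen batch-norm layers keep updating running
statistics but their affine parameters are not trained.

Augmentation draws, each with independent probability 0.5: rotation within
+/-15 degrees, zoom +/-10%, translation +/-10% of the side, and
horizontal/vertical flips; rotation/zoom/translation compose into a single
bilinear warp so the patch is resampled at most once.

Cross-validation is nested and patient-grouped: 5 stratified outer folds
(round-robin dealing continued across classes, so 104 patients split
21/21/21/21/20), and a 3-fold inner assignment of each outer fold's
training+validation patients. By default inner fold 1 is the validation
set for early stopping; `inner_rotations = TRUE` trains all three rotations
and keeps the best-validation model. Two protocol decisions deliberately
deviate from the description they implement:

* **Weight carry-over.** Continuing fold f from fold f-1's weights lets a
  model see (indirectly) patients that belong to fold f-1's test set —
  a leakage-prone protocol. The default is a fresh initialization per fold;
  `weight_carryover = TRUE` reproduces the carry-over exactly, and both
  modes are recorded in the run object.
* **Fold-local seeding.** Each fold's randomness (initialization, batch
  order, dropout, augmentation) derives from `seed + 7919 * fold`, so with
  carry-over off, fold results are independent of fold processing order.

ROI-level metrics (accuracy, precision, recall, F1, all percentages, with
infection as the positive class and argmax/0.5 decisions) are computed per
outer fold and averaged as mean +/- sample sd — per-fold averaging, not
pooling. The mean ROC curve is the vertical average of per-fold ROC curves
(infection-class probability, via pROC) on a 0.01-spaced FPR grid with a
+/-1 sd band. Strict patient-wise accuracy applies the asymmetric clinical
rule (infected patient correct if *either* ROI is flagged; control correct
only if *neither* is), per class and per fold; discordance is the fraction
of patients whose left/right predictions disagree. Whether the fold-level
table upstream is ROI-level or patient-level is not fully explicit; this
package treats fold metrics as ROI-level and reports the strict
patient-wise rule separately, which reproduces the separation of the two
result presentations.

## Problem sizes and determinism

The test suite and the synthetic experiments run at reduced scale as the
package's own standard study conditions: phantom cohorts of 20 patients
per class, the `tiny` backbone at 32 x 32 input, 50 selected features, the
desk schedule (`train_config_desk()`: phase-1 cap 20 epochs, phase-2 cap
5, batch 16). The full-scale DenseNet-201-style fusion model is built and
probed for its internal geometry (channel counts and grid sizes), which is
exact and independent of training. All randomness flows from explicit
seeds; identical seeds give identical cohorts, fold plans, initial weights
and training trajectories.

## Known limitations

* The phantom's class signal is, by construction, expressible in the
  package's own feature families; transfer to clinical CSF imaging is
  untested and untestable without data.
* The mobilenet-style backbone is a topological stand-in (no
  inverted-residual blocks, squeeze-excitation, or hard-swish).
* Pure-R convolutions make full-scale *training* impractical; the
  full-scale models are used for geometry and inference-path verification,
  and training runs use the reduced configuration.
* Marching-squares perimeters retain a residual positive bias (~2-5% on
  curved shapes) even after corner smoothing; sphericity is accordingly a
  slight underestimate.
* No significance testing between models is provided; the upstream
  comparison test is unnamed, and inventing one here would suggest a
  precision the protocol does not have.
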