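---
title: "Staging brain-slice phantoms: models, losses and design choices"
author: "gmstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging brain-slice phantoms: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural MRI of Alzheimer's disease shows two robust anatomical signatures:
thinning and dimming of the cortical gray-matter (GM) ribbon and enlargement
of the CSF-filled ventricles, progressing from cognitively normal (CN)
through mild cognitive impairment (MCI) to Alzheimer's disease (AD). gmstage
implements a four-phase 2D slice pipeline around these signatures:

1. **Whole-brain segmentation** — a vanilla U-Net (depth 4) isolates the
   brain from the slice.
2. **Gray-matter segmentation** — a multi-layer U-Net (depth 3, skip
   connections at every level) extracts the GM ribbon, trained under a
   class-balanced binary cross-entropy (or soft Dice) loss.
3. **Hybrid classification** — a multi-scale convolutional feature head
   (parallel 3×3 / 5×5 / 7×7 branches, LeakyReLU, max pooling, adaptive
   average pooling, dropout) reads a frozen backbone's feature map, is
   trained by categorical cross-entropy, and its concatenated feature vector
   feeds a standardised, grid-searched kernel SVM over {AD, CN, MCI}.
4. **Saliency explanation** — the absolute input gradient of the target
   class score, normalised per map, blurred, edge-overlaid and quantified
   over four image quadrants.

Clinical MRI datasets for this task are access-restricted, so the package is
exercised end to end on synthetic brain phantoms with exact ground truth.

## The phantom generator

A phantom is five concentric tissue regions at a reference scale of 224
pixels: background (0), a bright skull rim (0.95, radius 94–100), a dark CSF
ring (0.12, radius 88–94), a GM annulus of class-dependent thickness and
intensity ending at radius 88, and a bright WM core (0.80), plus a central
CSF-filled elliptical ventricle. Class effects are deliberately strong so
small CPU runs converge:

| class | GM thickness (px @224) | GM intensity | ventricle radius (px @224) |
|-------|-----------------------:|-------------:|---------------------------:|
| CN    | 9                      | 0.60         | 6                           |
| MCI   | 7                      | 0.55         | 8                           |
| AD    | 5                      | 0.50         | 11                          |

Geometry scales linearly with image size. Per-sample variation comes from a
multiplicative shape jitter (default ±8% on radii, thickness and ventricle
axis, plus a centre offset) and additive Gaussian intensity noise (default
sigma 0.02, clipped to [0, 1]). Per-sample seeds are `global seed + record
index`, so datasets are reproducible record by record. No public statistics
of the clinical images this emulates are available, so these magnitudes are
design choices, not estimates: passing tests demonstrate that the
*machinery* recovers a planted, well-separated signal, not that it would
reach any particular accuracy on clinical data. The phantoms deliberately
omit anatomy, bias fields, Rician noise and partial-volume effects.

## Segmentation: losses and the class-balance weight

The balanced cross-entropy over a probability map \(p\) and binary mask
\(y\) is

\[ L = \mathrm{mean}\big( -\beta\, y \log p - (1-\beta)(1-y)\log(1-p) \big), \]

with predictions clipped to \([10^{-7}, 1-10^{-7}]\). `beta = "auto"` sets
\(\beta\) to the background-pixel fraction of the training masks, so sparse
foreground (the GM ribbon is under 10% of a 64-pixel slice) is up-weighted.
The soft Dice alternative is \(1 - (2\sum p y + s)/(\sum p + \sum y + s)\)
with smoothing \(s = 1\), which makes two empty masks score a loss of 0.

Numerical and optimisation choices, all tunable: prediction threshold 0.5;
3×3 "same" convolutions with ReLU; 2×2 max pooling; 2×2 stride-2 transposed
convolutions; filters doubling per level from a base of 32; He-scaled
Gaussian initialisation; Adam (defaults: learning rate 1e-4, batch size 8,
100 epochs) with the best epoch selected by validation Dice. Forward and
backward passes run as single-precision BLAS matrix products over im2col
buffers; training is bit-reproducible for a fixed seed and thread count.

**Desk-scale learning rate.** The reference recipe (1e-4, 100 epochs) spends
most of its budget escaping the over-segmented plateau that the strongly
foreground-weighted loss induces early in training. The scaled-down study
runs used throughout the tests (150 slices at 64×64, 15 epochs) therefore
use a learning rate of 1e-3 — the same optimiser and loss, one decade faster
— which reaches validation Dice ≈ 0.98 on GM annuli within that budget. This
is a property of the shortened schedule, not of the loss.

## Classification

The backbone is pluggable behind `extract_features()`: any object mapping a
slice to a C×H′×W′ activation map fits the contract (a large pretrained
classification backbone, e.g. an EfficientNet-B0 final stage with 1280
channels at stride 32, is the natural production choice). The package ships
a compact random-initialised CNN backbone so that the whole pipeline is
self-contained and deterministic; with a frozen random backbone the
*trained* multi-scale head carries the discriminative work, which is exactly
what the tests probe.

The head's three branches use kernel sizes 3/5/7 (a single-branch variant
supports the single-scale ablation), 128 branch channels by default (32 in
the scaled-down runs), LeakyReLU slope 0.01 and dropout 0.3 (training only,
inverted scaling). Branch outputs are max-pooled, average-pooled to 1×1 and
concatenated in fixed order, giving a feature vector of length
3 × branch channels. A linear softmax layer trained by categorical
cross-entropy (Adam, learning rate 1e-4 reference / 3e-3 desk scale, batch
32) sits on top during head training.

Features are standardised by a scaler fitted on training data only
(zero-variance dimensions keep scale 1), then classified by one-vs-rest
SVMs: the binary decision is the kernel sum
\(f(x) = \sum_i \alpha_i y_i K(x_i, x) - \rho\) with
\(K = \exp(-\gamma\lVert x_i - x\rVert^2)\) (or the inner product for the
linear kernel), and the multi-class label is the argmax of the per-class
scores — a choice that also exposes the continuous scores the one-vs-rest
ROC analysis needs. The grid search covers kernels {rbf, linear} ×
C {0.1, 1, 10} × gamma {"scale" = 1/(d·var X), "auto" = 1/d}, scored by
stratified 5-fold cross-validated accuracy; ties resolve to the documented
grid order (rbf first, larger C first, "scale" before "auto"). Underlying
binary fits use libsvm, whose decision sign follows the class seen first in
the data; the stored dual coefficients are re-oriented after fitting so a
positive score always means "this class", and the package's own kernel-sum
predictor is cross-checked against libsvm's decision values in the tests.

The McNemar comparison of two classifiers uses the uncorrected statistic
\((b-c)^2/(b+c)\) on the discordant counts against a chi-squared reference
with 1 df (continuity correction available behind a flag); \(b + c = 0\)
yields statistic 0 and p = 1.

## Saliency

Gradients flow through the differentiable softmax-head path — backbone
convolutions included — never through the SVM, whose sign decision has zero
gradient almost everywhere; passing an SVM raises an error pointing to the
head path. Maps are \(|\partial(\text{class score})/\partial \text{pixel}|\)
normalised per map to maximum 1 (an all-zero map stays zero), matching the
per-image reading of "brighter = more influential". Overlays blur the map
(Gaussian sigma 2 px default), optionally mix in a Sobel edge magnitude of
the slice (weight 0.3), and tint a single colour channel — red for AD, blue
for MCI, green for CN — alpha-blended over the grayscale slice. Quadrants
are numbered row-major from the top left; for even image sides the four
quadrant means average exactly to the global mean.

## Scaled-down study sizes

The test-suite and acceptance-script runs use, as the package's own desk
-scale study design: 64×64 phantoms; 150 training slices / 15 epochs for the
multi-layer GM segmenter (base 32); 80 slices / 5 epochs for the vanilla
brain segmenter (base 16); 300 phantoms per class with a 60/20/20 stratified
split, 10 head epochs and the full 12-cell SVM grid for classification; 5
seeds (42–46) for directional comparisons. Pipeline runs repeat over the
seed list and report mean ± sd, and two runs with identical configuration
produce byte-identical metric summaries.

## Known limitations

- Phantoms are radially symmetric cartoons; no conclusions about clinical
  MRI performance follow from phantom accuracy.
- The 2D engine is single-threaded per image and CPU-oriented; it is not a
  general deep-learning framework (fixed layer vocabulary, no batching
  across images inside a GEMM).
- Augmentation is applied to the training split only, avoiding the leakage
  risk of augment-then-split.
- The middle-slice rule uses round-half-up counting with a floor-centred
  start; slice indices are zero-based to match on-disk slice numbering.
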