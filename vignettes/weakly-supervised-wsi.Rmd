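---
title: "Weakly supervised whole-slide classification with hard tile mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised whole-slide classification with hard tile mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsimine)
```

## The problem

Digitized histopathology slides (whole-slide images, WSIs) are far too large
for a convolutional network to consume whole, and clinical archives rarely
come with pixel-level lesion annotations: what a pathology report provides
is one label per slide — here, *adenocarcinoma* versus *benign*. wsimine
implements a complete training and evaluation pipeline for this setting.
The slide is decomposed into fixed-size square tiles over detected tissue, a
CNN scores each tile, and the slide-level prediction is the **maximum tile
probability** (multiple-instance max aggregation: one confidently positive
tile suffices to call a slide positive). Training uses only the inherited
slide label on each tile — the package never reads lesion coordinates during
training, and the sampling layer consumes manifests without the ground-truth
mask columns, so weak supervision is enforced by construction.

## Pipeline

1. **Tissue detection.** The image is converted to grayscale (ITU-R 601
   weights 0.299/0.587/0.114) and thresholded with Otsu's method: the 8-bit
   level maximizing the between-class variance of the 256-bin histogram,
   scanning all candidates, ties broken toward the lowest level. Tissue is
   defined as gray *strictly below* the threshold — tissue is darker than
   the near-white background. No morphological cleanup is applied beyond an
   optional small-object removal (off by default).
2. **Tiling.** Tiles of side `tile_size` are enumerated on a raster grid
   (0-based origins, x right / y down, half-open extents) with stride
   defaulting to the tile size (non-overlapping) and emitted when at least
   `min_tissue_frac` (default 0.1) of their pixels are tissue. Both the
   prediction-time stride and the minimum-tissue rule are configuration
   knobs rather than fixed constants, since neither has a canonical value.
3. **Balanced random sampling.** Training slides enter a shuffled queue
   that alternates labels (positive, negative, ...). Each pair of drawn
   slides contributes `batch_size / num_labels` tiles each (16 + 16 at the
   default batch of 32), drawn uniformly from the slide's tile pool —
   without replacement when the pool is large enough, with replacement
   otherwise. When one label's slide list empties before the other's within
   an epoch, slides of that label are re-drawn uniformly with replacement,
   so alternation continues and every training slide contributes tiles in
   every epoch. An *epoch* is one pass over the queue: `max(n_pos, n_neg)`
   alternating pairs.
4. **Hard tile mining.** Once the validation loss has not improved for
   `switch_patience` (2) epochs, training switches — once, irreversibly —
   to hard-example mining: the current model (weights frozen) is applied to
   each training slide's full tile grid in queue order; the k (8) tiles
   most inconsistent with the slide label are selected (highest positive
   probability on negative slides, lowest on positive slides; ties broken
   in row-major tile order); selected tiles accumulate in a FIFO pool, and
   whenever the pool holds N (256) tiles, those are released for training
   in batches of 32, in arrival order.
5. **Optimization.** Adam (β₁ = 0.9, β₂ = 0.999), binary cross-entropy on
   a single sigmoid logit, initial learning rate 0.001 multiplied by 0.95
   every 2 epochs, no gradient clipping. Early stopping ends training after
   `early_stop_patience` (10) epochs without a new validation-loss minimum,
   and the checkpoint with the lowest validation loss is returned.
6. **Evaluation.** Slide scores feed a threshold-sweep ROC (thresholds =
   all distinct scores plus sentinels; positive call at score ≥ t, so ties
   are called positive), trapezoidal AUC, log loss, and
   accuracy/sensitivity/specificity/F1 at a default operating threshold of
   0.5 — the threshold is exposed because no canonical value exists for it.
   Every metric carries a 95% percentile bootstrap confidence interval from
   1000 resamples of *slides* (slides, not tiles, are the sampling unit of
   the reported metrics); resamples that lose a label class are re-drawn so
   the iteration count stays fixed, and the interval endpoints are exact
   order statistics of the bootstrap distribution, deterministic given the
   seed.

## The backbone and partial fine-tuning

The reference backbone (`tiny_cnn`) is three blocks of 3×3 stride-2
convolution → batch normalization → ReLU (8, 16, 32 channels), global
average pooling, and a single-logit linear head. It is implemented directly
on base matrix algebra: convolutions are evaluated as an im2col gather
followed by one BLAS matrix product, and the backward pass is the exact
adjoint (verified against numerical differentiation in the test suite).
Batch normalization uses batch statistics during training and running
statistics at inference, which is why tile predictions are independent of
how tiles are batched.

Two fine-tuning modes honor the same contract:

* `finetune = "partial"` — only the batch-normalization affine parameters
  (scale and shift) and the final classifier's weights and bias are
  trainable; convolution kernels stay bit-identical for the whole run. This
  is the standard recipe for adapting a *pretrained* backbone.
* `finetune = "full"` — every parameter trains. This is the appropriate
  mode for the from-scratch `tiny_cnn`: partial fine-tuning presumes
  informative pretrained filters, and with random frozen kernels the pooled
  features separate the synthetic textures only weakly. End-to-end runs in
  this package therefore train in full mode, while the partial mode is the
  contractual surface for pretrained backbones (an EfficientNet-style
  backbone is accepted by the configuration but requires user-supplied
  weights; the package ships none).

`lr_at_epoch`, the mining switch, and early stopping all use 0-based epoch
indices; "improvement" means a strict decrease of the running minimum
validation loss (zero tolerance). The validation loss itself is the mean
binary cross-entropy over a fixed, seeded subsample of validation tiles
(default 64 per slide, the same tiles every epoch) with labels inherited
from slides. Note a structural property of weak supervision: on positive
slides most tiles are genuinely benign tissue, so the tile-level validation
loss has a floor well above zero, and the hard-mining phase — which
deliberately trains on the lowest-probability tiles of positive slides —
can raise it. The lowest-validation-loss checkpoint rule is what protects
the final model.

## The synthetic slide generator

The generator exists so that every stage is testable without clinical data.
It emulates exactly the features the pipeline depends on:

* a near-white background (gray 245 ± 1.5) cleanly separable by Otsu
  thresholding;
* darker tissue (mean gray 145, marginal SD 15) laid out either as
  elongated rotated rectangles with aspect ratio ≥ 8:1 (needle-biopsy-like
  cores) or as unions of overlapping discs (resection-chip-like blobs);
* on positive slides, a connected lesion region occupying a controllable
  fraction of the tissue area, with a texture that differs from benign
  tissue **only in its spatial correlation length**: both textures are
  Gaussian-smoothed noise with identical mean and marginal variance, benign
  at smoothing σ = 3 px, lesion at σ = 3·exp(−contrast/50) px (≈ 0.9 px at
  the default contrast of 60). Because the per-pixel intensity
  distributions coincide, no single-pixel threshold can separate the
  classes — a classifier must integrate texture at tile scale, which is
  precisely the ability the pipeline is supposed to learn.

The lesion is grown from a random seed inside the largest tissue core by
taking that core's nearest tissue pixels (Euclidean distance from the seed)
until the target pixel count is reached, spilling into the next-nearest
core only if one core cannot hold the requested fraction. Within a convex
needle core the region is exactly connected; for blob cores it is connected
up to disc overlaps. The emitted ground-truth tissue and lesion masks are
used only by tests and evaluation, never by training.

All randomness flows from one master seed through named substreams (a
string-hash seed derivation), so a cohort regenerates bit-identically from
its manifest parameters. "10×" slides are generated at half the linear
resolution of "20×" ones; magnification is otherwise nominal metadata, and
the texture correlation lengths are defined in pixels at whichever
resolution is generated.

What the generator does **not** emulate: staining variation, pen ink,
scanner artifacts, tissue folds, cautery damage, multi-resolution pyramids,
or the morphological diversity of real carcinoma. Passing the end-to-end
tests therefore demonstrates that the pipeline's machinery — masking,
balanced sampling, mining, optimization, aggregation, evaluation — works as
specified on a learnable texture task; it does not certify clinical
performance.

## Numerical and design choices

* Luminance weights 0.299/0.587/0.114 (ITU-R 601) for RGB→gray.
* Otsu ties broken toward the lowest threshold; constant images are
  rejected as degenerate rather than silently thresholded.
* Tile coordinates are 0-based, half-open, x right / y down, everywhere.
* Top-k/bottom-k tie-breaks are stable row-major (y, then x).
* Positive call at score ≥ threshold (ties positive).
* Probability clipping at 1e-7 in training losses, 1e-15 in slide-level
  log loss.
* Oversampling re-draws uniformly with replacement from the exhausted
  label's slide list; released mining batches are trained as released
  (FIFO, no re-balancing), since release is defined purely by count.
* The same validation split gates both the mining switch and early
  stopping; there is only one validation set.
* Default maximum of 100 epochs as a safety cap; runs in this package stop
  by early stopping well before it.

## Problem sizes used by the tests

Unit tests run on 256 px slides with 64 px tiles (8 slides). The end-to-end
property check trains the tiny CNN from scratch on a 40/10/20-slide cohort
of 1024 px slides with 128 px tiles and lesion fraction 0.3 — chosen as the
smallest configuration on which slide-level ROC-AUC ≥ 0.95 is a meaningful
bar: roughly 25–50 tissue tiles per slide, two training phases, and early
stopping all engage at this size. `scripts/acceptance.R` reruns that same
configuration from scratch and reports the test-set metrics with their
bootstrap intervals.

## Known limitations

* The pure-R backbone is adequate for the tile counts above but is not a
  GPU deep-learning framework; swapping in a stronger backbone means
  implementing the small forward/backward/parameter-mask contract.
* Binary labels only; the queue generalizes to more labels but only the
  two-label case is exercised.
* Single-resolution PNG/TIFF input; pyramidal formats are out of scope.
* The bootstrap quantifies sampling uncertainty over slides, not model
  uncertainty: retraining with another seed produces a different model
  whose variability the intervals do not cover.
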