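---
title: "Counting by density-map estimation: model, losses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting by density-map estimation: model, losses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densicount)
```

## Why density maps

In aerial survey mosaics of colonial animals, each individual occupies only
about 5 × 5 pixels and neighbours may nearly touch. Detection pipelines
must localise and classify each object, which fails in exactly this regime;
density-map estimation side-steps localisation. Each annotated point is
replaced by a Gaussian kernel of unit mass, producing a field whose
integral over any region equals the expected number of objects in it.
The learning problem becomes image-to-image regression, and counting
becomes integration.

The assumptions this encodes are worth stating. A *fixed* bandwidth
(σ = 4 px by default) assumes objects are close to identical in size on the
ground — true for ortho-rectified imagery of a single species at a fixed
resolution. An adaptive, nearest-neighbour-scaled bandwidth is available
(`gen_config(adaptive = TRUE)`) for perspective-distorted imagery, but it
is off by default and untested against real survey data here.

## Target construction

`generate_density_map()` evaluates each kernel at pixel centres on a
`(2·4σ+1)²` window centred at the point's nearest pixel and divides by the
*window* sum. Two consequences:

* a point whose window lies inside the image contributes mass exactly 1
  (to floating-point precision), so integration really is counting;
* a kernel clipped by the image border keeps only its in-frame mass.
  This is deliberate and is what makes counts additive when a scene is cut
  into tiles: an object straddling a tile border contributes fractional
  mass to each side, summing to 1 across the scene. `tile_scene()` crops
  density tiles from the full-scene map for exactly this reason, while each
  point annotation is assigned to the single tile containing its centre.

The learning target at network resolution, `downsample_density()`, is a
non-overlapping 8 × 8 block *sum* (never a mean), so the mass is preserved
exactly; non-divisible shapes are zero-padded bottom/right first, matching
the network's own padding convention. The segmentation target is the strict
indicator `S = 1(D > ε)` with ε = 1e-3 density units: cells at exactly the
threshold are background.

Coordinates are 0-based, `x` is the pixel column, `y` the pixel row, and
pixel centres sit at integer coordinates. The convention is stated once
here and used everywhere, including the annotation CSV
(`image_id,x,y`; zero-count images are carried by the manifest).

## The network

The backbone is VGG-19 truncated before its last max-pool: sixteen 3 × 3
convolutions and four stride-2 pools, leaving 512-channel features at 1/16
resolution, upsampled ×2 bilinearly to 1/8. Both branches consume the same
upsampled features (the segmentation branch sees them *unmasked*; only the
density branch sees masked features — the architecture is a cycle
otherwise). Each branch is `conv3×3 → ReLU → conv3×3 → ReLU → conv1×1`
with channels shrinking 512 → 256 → 64 → 1 by default ("halve, then
shrink"; the intermediate widths are configurable since only the endpoints
are structurally fixed). The density head is ReLU-activated (non-negative
density); the segmentation head is a sigmoid.

The feature mask `M = 1(S_pred ≥ 0.5) + α·1(S_pred < 0.5)` with α = 0.1
multiplies the features point-wise, broadcast over channels. Numerical
choices that matter for reproducibility:

* **Mask gradient.** The mask is a constant in the backward pass. The
  indicator has zero derivative almost everywhere, and at the threshold
  itself the derivative is undefined; detaching it avoids an ill-defined
  backward pass without changing the attainable gradients. (This is also
  visible in finite-difference tests: perturbing the segmentation head of
  an *untrained* model, whose probabilities all sit at ≈ 0.5, flips mask
  cells and produces a large jump — a discontinuity of the model, not an
  error of the gradient.)
* **Bilinear upsampling** uses the half-pixel-centre convention (corners
  not aligned), stated so golden tests are bit-exact.
* **Padding.** Inputs are zero-filled bottom/right to the next multiple of
  16 (four pooling stages; anything else drops pixels). The reported count
  is the mass of the fused output over the *padded* frame. The padded band
  is not cropped away before integration, because the convolutional
  receptive field bleeds a little (usually tiny) response into it and
  cropping would make the count depend on whether the caller pre-padded
  the image; with the full-frame convention the count is exactly
  padding-invariant, and the unpadded size travels with the returned map.
* **Initialisation.** Branch and head weights are N(0, 0.01), following
  the training recipe for the non-pretrained layers. The backbone in
  from-scratch mode uses He initialisation: the N(0, 0.01) recipe is tuned
  to layers sitting on top of a pretrained backbone, and applied to all
  sixteen backbone convolutions it attenuates the signal to nothing.
  Pretrained backbone weights can be supplied from a file
  (`use_pretrained_backbone`), but nothing in the package depends on a
  download.
* **Input normalisation** is per-channel `(x − 0.5) / 0.25`, appropriate
  for `[0, 1]`-scaled imagery; the constants live in `model_config()`.

At inference, `D_out = D_pred ⊙ 1(S_pred ≥ 0.5)` (threshold inclusive)
zeroes the regressor's residual response on background, which is safe
precisely because the masked loss (below) never asked the regressor to be
accurate there.

## The loss

The density branch is supervised by a multi-scale structural similarity
loss. The similarity index of two maps is computed from whole-map
statistics (means, variances with 1/M normalisation, covariance):

```
SSIM(X, Y) = (2 μX μY + C1)(2 σXY + C2) / ((μX² + μY² + C1)(σX² + σY² + C2))
```

with C1 = 0.01 and C2 = 0.03 taken literally as additive constants. Three
interpretation points are settled here as the package's own reading:

* The index is the *standard similarity* (1 for identical maps). The loss
  applies `1 − SSIM` outside it; keeping an extra leading `1 −` inside the
  index would invert its meaning and break the identity `SL(X, X) = 0`.
* Statistics are whole-map, not sliding-window: the multi-scale pooling
  already provides locality, and a windowed variant
  (`ssim_index(..., window = )`) is available but off by default.
* `Pool_i` is average pooling with kernel = stride = `2^(i−1)` (level 1 is
  the identity), N = 3 levels by default. Odd trailing rows/columns are
  dropped (floor division); if a map is smaller than the coarsest kernel,
  the level count is reduced with a warning rather than failing.

The trained variant `SL*` masks both maps by the *ground-truth*
segmentation before pooling. Background cells vastly outnumber the few
cells carrying real mass; unmasked, the regressor spends its capacity
matching near-zeros and systematically underestimates the peaks that
dominate the count. `SL*` reduces exactly to `SL` under an all-ones mask
and to 0 under an all-zero mask (both maps become identically zero).

The segmentation branch gets a class-balanced cross-entropy with the
background term weighted by h = 0.5, probabilities clamped to
`[1e-7, 1 − 1e-7]` before the logs (the clamp region is treated as flat in
the gradient). The total is `SL* + λ·CE` with λ = 0.1: density regression
is the main task.

All loss gradients are analytic (the SSIM gradient in particular follows
from the quotient rule on the five whole-map statistics) and are verified
against central finite differences in the test suite.

## Training procedure

`split_dataset()` shuffles once (seeded) and splits 3:1:1, flooring the
validation/test sizes and giving the remainder to training. Augmentation
is a random `crop_size` crop (256 px at full scale) plus a horizontal flip
with probability 0.5 — the flip probability is the natural choice where
only "random flipping" is specified. The crop window and flip are applied
jointly to the image and to the *precomputed full-resolution* density map;
the crop is then sum-pooled ×8 and thresholded into the two targets. Doing
density generation before cropping (rather than regenerating from the
surviving points) preserves fractional mass at crop borders; the order of
operations is this package's choice where the recipe is silent.

One epoch is one pass over the training list with one random crop per
image; batches of 16 take one Adam step (lr 1e-5, weight decay 1e-4 folded
into the gradient) on the mean per-image gradient. After epoch 100, every
epoch is validated on the *full*, uncropped validation images through the
fused inference pathway — the same pathway used at test time — and the
checkpoint minimising `val MAE + val RMSE` is kept, ties going to the
earliest epoch. Training aborts with a diagnostic on a non-finite loss.
Runs are deterministic given the config seed, and `resume =` continues a
run with its optimizer state.

The defaults above are the full-scale recipe (pretrained VGG-19, hours of
GPU time). For desk-scale work the package uses the `"tiny"` backbone
(identical four-pool structure, widths 8–64) trained from scratch, for
which Adam's conventional 1e-3 learning rate is appropriate — 1e-5 is
specific to fine-tuning a pretrained backbone.

## What the synthetic generator does and does not emulate

`generate_scene()` renders ~5 px elliptical Gaussian-profile blobs with
per-object shape/intensity jitter on flat, textured (smoothed-noise) or
illumination-gradient backgrounds, at positions rejection-sampled with a
minimum spacing of 2 px (near-touching, as in dense colonies). Counts are
drawn per density level L0–L4, including pure-background images, mirroring
the level composition of survey archives. Everything is seeded and
bit-reproducible.

It emulates the *statistics* of the counting problem — object size,
contrast, crowding, background heterogeneity, the count distribution — but
not biological texture, shadows, terrain parallax, species mixtures or
annotation noise. Passing tests on this data therefore demonstrates that
the pipeline's mechanics (targets, losses, gradients, selection,
evaluation) are correct and that the model can learn to count blob-like
objects; it does not certify field accuracy on real imagery, which depends
on a full-scale backbone, pretrained features and real training data.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run on one CPU core comfortable: 128 px scenes for the learning check
(106 images split 64/21/21, tiny backbone, 64 px crops, batch 8,
30 epochs, validation from epoch 11), 896 px scenes for tiling, and
8–16 px maps for the loss oracles. These sizes are stated here because
they are the package's desk-scale reference configuration, also used by
`scripts/acceptance.R`. On those held-out synthetic tiles the tiny model's
MAE beats the predict-the-training-mean baseline by a wide margin (the
script reports the exact figures per seed).

## Known limitations

* Whole-map SSIM makes the structural loss global per crop; very large
  crops dilute its sensitivity to local errors (the pooled levels
  mitigate, not remove, this).
* The count is non-negative by construction but not integer; rounding is
  intentionally *not* applied before metrics, since the error metrics are
  defined on raw counts.
* Per-level metrics are computed within level bands assigned from
  ground-truth counts; levels with no images report `NA`, not 0.
* The CPU implementation is practical for the tiny backbone and for
  inference; full-scale 600-epoch training of the VGG-19 backbone is out
  of reach without accelerator hardware, which is why the package treats
  the full-scale configuration as supported-but-external.
```{r}
sessionInfo()
```
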