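---
title: "Segmenting skull structures in CBCT with a 3D transformer U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting skull structures in CBCT with a 3D transformer U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam computed tomography (CBCT) is the workhorse 3D modality of
orthodontics and oral-maxillofacial surgery. Manual segmentation of the
skull structures a surgeon needs — mandible, maxilla, cranial base,
cervical vertebrae, skin — takes hours per scan and is the bottleneck of
quantitative craniofacial analysis. The scans are also heterogeneous:
voxel spacings from 0.16 to 0.5 mm, scanner- and centre-dependent
intensity ranges (CBCT intensities are not calibrated Hounsfield units),
varying fields of view, and low signal-to-noise ratio.

`cbctseg` implements an automatic segmentation pipeline for this setting
end to end: geometry-aware volume IO and resampling, percentile-based
contrast normalization, a UNETR-style network (vision-transformer encoder,
convolutional U-shaped decoder), random-crop training with a combined
Dice + cross-entropy loss, sliding-window whole-volume inference,
connected-component/fill-hole post-processing, and the voxel-wise metric
suite used to evaluate such models (Dice, F2, accuracy, recall,
precision, AUPRC against its prevalence baseline). One binary model is
trained per structure.

Because clinical CBCT datasets are private, the package ships a synthetic
phantom generator that reproduces the statistical structure the pipeline
must cope with, so that every stage — including a complete small training
run — is testable on any machine with no data download.

## Pre-processing

**Resampling.** All scans and segmentations are resampled to an isotropic
working grid (0.4 mm by default) — linear interpolation for images,
nearest-neighbour for labels. Output grid sizes follow
`ceil(size * spacing / target)`, which never crops anatomy; origin and
direction are preserved, and all resampling happens in physical (LPS
world) space, so non-axis-aligned direction matrices are handled
uniformly. The resampler was cross-checked against SimpleITK on shared
inputs (agreement to ~1e-14 for linear interpolation, exact for
nearest-neighbour). Out-of-domain voxels are filled with the image
minimum (air) or 0 (labels).

**Contrast adjustment.** Intensities are windowed between the `x_min_pct`
and `x_max_pct` percentiles (defaults 1% and 99%) of the cumulative
intensity distribution *ignoring the background*, then rescaled to [0, 1].
"Background" is operationalized as the modal intensity: in CBCT the air
outside the field of view dominates the histogram and is near-constant,
so the mode is a robust stand-in when no numeric background value is
recorded. When an image has more distinct values than histogram bins
(1024 by default) the cumulative curve is binned and only the modal bin
is excluded; percentiles are then read off bin right edges. Two
boundary choices are deliberate:

* the percentile endpoints 0 and 100 fall back to the global minimum and
  maximum, so `(0, 100)` is a plain min-max rescale and the operation is
  idempotent on its own output;
* an image whose non-background voxels take a single value raises a
  degenerate-contrast error rather than returning an arbitrary field.

**Label canonicalization.** Ground-truth masks arrive with
centre-specific label values and sometimes hollow structures. They are
collapsed to binary and internal cavities are filled: a background
region counts as a cavity when it has no 6-connected (face-adjacent)
path to the grid border. The strict background connectivity fills more
aggressively, which matches the intent of solid bone masks; foreground
operations use the dual 26-connectivity.

## The network

A cubic window (128 voxels at deployment scale) is divided into
non-overlapping cubic patches (16 voxels), each flattened and projected
to the transformer width; a learned position embedding is added. The
encoder is a pre-layer-norm transformer (GELU feed-forward; at deployment
scale: hidden 768, feed-forward 3072, 12 heads, 12 layers). The decoder
reshapes tapped token sequences back into coarse feature grids and
upsamples them with stacked kernel-2/stride-2 transposed convolutions,
with channel widths `feature_size * {8, 4, 2, 1}`; the deepest tap feeds
the bottleneck, shallower taps merge in at the matching resolutions, and
the raw input joins at full and half resolution through learned 3x3x3
convolutions (expressed as linear maps over each voxel's
27-neighbourhood; the half-resolution branch sees the 2x mean-pooled
window). A final 1x1x1 head produces per-class scores; softmax gives
per-voxel probabilities.

Published descriptions of this architecture leave several details open;
the choices here are: 12 encoder layers with skip taps at layers
{3, 6, 9, 12} (the defaults of the architecture the pipeline builds on),
pre-layer normalization, GELU activations (the sigmoid approximation
`x * sigmoid(1.702 x)`, accurate to ~1e-3 and substantially cheaper than
the exact normal CDF), and dropout after the attention and feed-forward
blocks (rate 0.05). The "sequence of 16 patches" phrasing in the source
description is read as a patch *edge* of 16 voxels (512 tokens at a
128-cube window); 16 patches of a 128-cube would be geometrically
inconsistent. Every dimension is configurable, so a CPU-sized
configuration exists for testing.

Because no deep-learning framework is part of the package's dependency
footprint, the network, its reverse-mode gradients, and the Adam
optimizer (with decoupled weight decay) are implemented in-package on
base-R matrix algebra. Gradients of every parameter group are verified
against central finite differences in the test suite (relative error
~1e-6); this check, not a framework, is the correctness anchor. The
output head's foreground bias is initialized at the log-odds of a 5%
foreground prior — the standard initialization for heavily imbalanced
segmentation, which avoids spending the first training epochs unlearning
a uniform prediction.

## Training

Per epoch, the training scans are cycled in groups of `N_i`; from each
scan `N_s` cubic crops are drawn with corners uniform over the grid
("anywhere in the scan" — deliberately not foreground-biased), giving
batches of `N_i x N_s` crops. Each crop is augmented:

| event | probability | magnitude |
|---|---|---|
| flip, per axis | 25% | — |
| 90-degree rotation, per axis | 25% | — |
| intensity shift (image only) | 50% | ±0.1, sign uniform |
| gamma change (image only) | 80% | exponent uniform in [0.5, 2] |

The source description lumps "flip and rotation" under one 25% figure;
here they are independent 25% events per axis. Geometric operations apply
identically to image and label; intensity operations skip the label, and
the image is re-clamped to [0, 1]. Empirical event frequencies are tested
against 99% binomial intervals at 10,000 draws.

The loss is the weighted average of the soft Dice loss
`1 - 2 sum(p g) / (sum(p^2) + sum(g^2))` and voxel-wise cross entropy;
with no published weights, both default to 0.5. The Dice loss carries a
smoothing term `eps = 1e-5` in numerator and denominator because the
printed form is undefined on all-background crops. Cross-entropy class
weights default to 1. Optimization is Adam (lr 1e-4, decoupled weight
decay 1e-5). After each epoch the model predicts every validation scan
with sliding-window inference (20% overlap, no cropping) and the
checkpoint with the best validation Dice is kept. Validation-time
augmentation is implemented as described in the source training loop and
is on by default, but can be disabled (`val_augment = FALSE`) when a
stable checkpoint-selection signal matters more than parity, as in the
scaled-down experiment below. One master seed fans out to independent
streams for split, crops, augmentation, weights and dropout, so runs are
exactly reproducible.

## Inference and post-processing

Whole volumes are predicted by sliding a window across the grid with
stride `floor(window * (1 - overlap))`, the final position per axis
clamped to end exactly at the volume edge, so every voxel is covered.
Overlapping window probabilities are blended by uniform averaging
(a Gaussian-weighted option exists behind a flag); the published runs
used 20% overlap for validation, 50% for test metrics, 80% for
high-precision output. Argmax with ties broken toward background gives
the raw segmentation. Post-processing keeps the largest 26-connected
component (size ties break toward the smaller lexicographic corner),
fills internal holes on the working grid — where the operation is
scale-consistent — and resamples to the original scan geometry with
nearest-neighbour interpolation. The output overlays the input scan
voxel for voxel.

## Evaluation

All metrics are computed on the binarized post-processed segmentation,
except AUPRC, which consumes the pre-argmax probability volume. The PR
curve sweeps all unique probabilities (or 1024 quantiles when there are
more), is anchored at recall 0 and at recall 1 (precision = prevalence),
and is integrated with the standard trapezoid
`sum (R[n] - R[n-1]) (P[n] + P[n-1]) / 2`. The source prints a difference
of precisions in the integrand, which integrates flat curves to ~0 and
cannot produce the reported values; it is treated as a typo and kept
available behind `integrand = "difference"` for auditability. The AUPRC
chance baseline equals foreground prevalence — the informative reference
under the ~1-10% prevalence of skull structures. Degenerate comparisons
(empty vs empty) raise rather than silently return 1, to surface
pipeline failures.

## The phantom family

A phantom is an ellipsoidal bright shell ("cortical bone", intensity 1.0)
with, by default, an internal cavity (soft-tissue interior, 0.2) and two
small disconnected bright satellites, on a dominant air background
(0.02), plus Gaussian noise (sd 0.05), a per-phantom gamma in
[0.85, 1.2], per-centre additive intensity offsets (0.08 between
consecutive centres), and anisotropic spacing drawn from [0.16, 0.5] mm.
Semi-axes of 22-30% of the grid put ground-truth prevalence at roughly
3-11%, matching the class imbalance of real bone masks. The ground truth
is the *solid* ellipsoid: the cavity makes fill-hole measurable, and the
satellites — bright but absent from the truth — give largest-component
filtering a testable effect size.

What the family does *not* emulate: anatomical shape detail, beam
hardening, metal artifacts, partial-volume effects at real bone
interfaces. Passing tests on phantoms therefore demonstrates that the
pipeline's machinery — normalization, learning, inference, post-
processing, metrics — is correct and learnable-from, not that any
particular clinical Dice will be reached on patient data.

## The scaled-down experiment

`run_scaled_experiment()` reproduces the training study in miniature,
sized for a single CPU: 20 phantoms of 64^3 from 2 pseudo-centres, split
70/10/20 per centre, a small network (32-voxel window, 16-voxel patches,
hidden 64, feed-forward 128, 2 layers with taps {1, 2}, 4 heads,
feature size 16, dropout 0.05), batches of `N_i = 1` scan times
`N_s = 2` crops — small batches favour optimizer steps over batch size at
the fixed learning rate — for at most 30 epochs with patience-8 early
stopping, then 50%-overlap sliding-window prediction and full
post-processing on the 4 held-out phantoms:

```{r}
library(cbctseg)
run <- run_scaled_experiment(seed = 1)
run$mean_dice          # post-processed test Dice, typically >= 0.8
run$per_phantom        # per-phantom metric suite
```

To keep a full multi-seed run affordable on one CPU, the experiment
validates every second epoch (`val_every = 2`); checkpoint selection
granularity is the only thing this changes.

The acceptance suite runs this experiment for three seeds and checks the
median mean-Dice against 0.80, and that post-processing improves the
aggregate test Dice on these satellite-bearing phantoms. The improvement
holds per seed but not always per phantom: when the network predicts an
imperfect shell that encloses a pocket of true background, fill-hole
converts that pocket to foreground and can cost a few thousandths of
Dice on that scan — an inherent property of the clean-up, usually far
outweighed by satellite removal. `scripts/acceptance.R` performs one
seeded run and writes all test-set quantities as JSON.

## Numerical choices and degenerate inputs

* Stride-2 transposed convolutions have kernel = stride, so each output
  voxel receives exactly one contribution; the op reduces to a matmul
  plus a fixed permutation, with exact gradients.
* Softmax and cross entropy subtract row maxima before exponentiation;
  probabilities are floored at 1e-300 inside logs.
* Argmax ties go to background; component-size ties go to the smaller
  lexicographic corner — both documented, deterministic choices.
* Volumes smaller than a crop or window are zero-padded symmetrically
  and cropped back after prediction.
* Empty label maps are rejected by `canonicalize_label` but pass through
  `largest_component` (and the post-processing pipeline) unchanged.

## Limitations

* The in-package network is CPU-bound; the deployment-scale
  configuration (128-voxel windows, 12 layers) trains impractically
  slowly here. The architecture is identical across scales, so the small
  configuration exercises the same code paths.
* DICOM support is read-only and covers the common export (uncompressed
  little-endian, single-frame slices); compressed transfer syntaxes and
  multi-frame objects are out of scope.
* Only binary (one-structure) models are supported, mirroring the
  one-model-per-structure design; multi-structure maps are produced by
  running several models and writing per-structure files.
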