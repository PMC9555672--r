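# cbctseg

Automatic multi-structure segmentation of cone-beam CT (CBCT) head scans
in R: a complete, tested implementation of the modern deep-learning
pipeline used for craniofacial structures (mandible, maxilla, cranial
base, vertebrae, skin) — from volume IO to evaluated segmentations.

Manual segmentation of a full face takes experienced clinicians on the
order of hours per scan; pipelines of this design produce it in minutes
at Dice scores above 0.95 on bone structures. The package targets
researchers who want an inspectable, dependency-light implementation of
every stage of that pipeline, exercisable at desk scale on synthetic
phantoms (clinical CBCT datasets are rarely shareable).

## What is inside

* **IO and geometry** — NIfTI-1, NRRD and DICOM-series reading with full
  physical geometry (spacing/origin/direction, LPS world coordinates);
  NIfTI/NRRD writing; physically correct linear and nearest-neighbour
  resampling (validated against SimpleITK to ~1e-14).
* **Pre-processing** — percentile-based contrast windowing to [0, 1]
  ignoring the air background; label binarization + 3D fill-hole.
* **Network** — a UNETR-style model: vision-transformer encoder over
  flattened cubic patches, convolutional U-shaped decoder fed by skip
  connections from intermediate transformer layers. Implemented
  natively, including reverse-mode gradients (finite-difference verified)
  and Adam with decoupled weight decay:

  `DL = 1 - 2 Σ pᵢgᵢ / (Σ pᵢ² + Σ gᵢ²)`, combined 1:1 with voxel-wise
  cross-entropy `−w_y log softmax(x)_y`.
* **Training** — per-centre 70/10/20 splits, uniform random crop
  sampling (N_i scans × N_s crops per batch), flip/rotation/intensity/
  gamma augmentation, per-epoch sliding-window validation, best-Dice
  checkpointing.
* **Inference** — sliding-window prediction with configurable overlap
  and uniform (or Gaussian) blending; argmax with background tie-break.
* **Post-processing** — largest 26-connected component, fill holes,
  resample back onto the exact input geometry.
* **Metrics** — Dice `2|A∩M|/(|A|+|M|)`, F2 `TP/(TP+0.2FP+0.8FN)`,
  accuracy, recall, precision, AUPRC (trapezoid over the PR curve) and
  its chance baseline (foreground prevalence).
* **Phantoms** — a seeded generator of skull-like volumes (bright shell,
  cavity, satellite artifacts, noise, per-centre contrast shifts) that
  makes the whole pipeline, including training, testable offline.

## Worked example

```r
library(cbctseg)

# a small end-to-end study on synthetic phantoms: generate, split, train,
# predict with sliding windows, post-process, evaluate
run <- run_scaled_experiment(seed = 1, verbose = FALSE)
round(run$mean_dice, 3)
#> [1] 0.854
round(run$per_phantom[, c("dice_post", "dice_raw", "recall", "precision",
                          "auprc_baseline")], 3)
#>   dice_post dice_raw recall precision auprc_baseline
#> 1     0.874    0.796  0.964     0.799          0.074
#> 2     0.871    0.776  0.974     0.787          0.071
#> 3     0.810    0.804  0.873     0.755          0.079
#> 4     0.863    0.786  0.980     0.771          0.068
```

`mean_dice` is the post-processed Dice on the four held-out phantoms;
`dice_raw` is the same before largest-component/fill-hole clean-up
(here worth about +0.06 Dice, mostly from filling the shell interior and
removing satellite artifacts). Recall exceeding precision reflects the
mild over-segmentation the F2 metric deliberately tolerates
(under-segmentation is clinically worse). `auprc_baseline` is the
foreground prevalence — the score an uninformative predictor would get —
showing the ~7% class imbalance these models work against.

Single scans go through the same machinery:

```r
ph <- generate_phantom(phantom_spec(seed = 7))      # stand-in for a scan
seg <- predict_pipeline(run$model, ph$image,
                        spec = sliding_window_spec(32L, overlap = 0.5))
dice_coefficient(seg, ph$label)
```

There is also a command-line front end (`inst/cli/cbctseg`) with
`generate-phantoms`, `train`, `predict` and `evaluate` subcommands.

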