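Package: cbctseg
Title: Multi-Anatomical CBCT Segmentation with a 3D Transformer U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for segmenting anatomical structures in
    cone-beam computed tomography (CBCT) head scans: geometry-aware volume
    input/output (NIfTI, NRRD, DICOM series) and resampling, percentile-based
    contrast normalization, a 3D UNETR-style network (vision-transformer
    encoder with a convolutional U-shaped decoder) with in-package
    reverse-mode gradients and Adam optimization, random-crop training with
    flip/rotation/intensity augmentation and a combined Dice plus
    cross-entropy loss, sliding-window whole-volume inference with overlap
    blending, connected-component and fill-hole post-processing, and a full
    voxel-wise evaluation suite (Dice, F2, accuracy, recall, precision,
    AUPRC with its prevalence baseline). A synthetic skull-like phantom
    generator makes every stage, including a small training run, testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
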