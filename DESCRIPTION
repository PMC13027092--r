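Package: milsij
Title: Gated-Attention Multiple Instance Learning for Sacroiliitis MRI Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level classification of sacroiliac-joint MRI slice stacks as
    active sacroiliitis versus healthy using gated-attention multiple instance
    learning (MIL). Each patient is a bag of axial slices with only a bag-level
    label; a convolutional backbone embeds every slice, a gated attention module
    (tanh x sigmoid branches) weights the slices, and the attention-weighted bag
    embedding is classified. Includes slice preprocessing (resize, 8-bit rescale,
    histogram equalization, ImageNet normalization), train-time augmentation,
    deterministic horizontal-flip test-time augmentation, patient-wise splitting
    with leakage guards, confusion-matrix metrics, ROC/AUC with Hanley-McNeil
    standard errors and power estimation, slice-level attention ranking,
    Grad-CAM saliency maps, and a seeded synthetic cohort generator that plants
    focal hyperintense lesions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
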