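Package: cgsnet
Title: Context-Guided Dual-Encoder Segmentation for Histopathology Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CGS-Net, a dual-resolution (detail plus context)
    dual-encoder transformer segmentation network for H&E-stained
    whole-slide images, together with the surrounding reproducible
    pipeline: a deterministic synthetic pyramidal-slide generator with
    ASAP-dialect polygon annotations, HSV/Otsu tissue masking and
    annotation rasterization, the five-category multi-pass patch
    extraction algorithm with quotas, overlap constraints and fallbacks,
    the staged training scheme (single-branch pre-training, weight
    transfer, cross-attention-only training, joint fine-tuning and
    combined retraining) with a focal-plus-dice loss, and pixel-pooled
    ROC/AUC and Dice evaluation. The multi-cross-attention fusion uses a
    zero-initialized query and identity keys/values/projection so that
    the dual model starts as a pure detail model and learns how to
    incorporate context. Networks are built on a small native
    reverse-mode autodiff engine so that everything runs at desk scale
    on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
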