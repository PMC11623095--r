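Package: msrunet
Title: Multi-Scale Reconfiguration Self-Attention U-Net for 2D Medical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transformer U-Net for 2D medical image segmentation built around
    multi-scale reconfiguration self-attention (MSR-SA): attention heads are
    grouped, each group is tiled into non-overlapping windows with an ascending
    dilation rate, keys are gathered by dilated sampling inside each window and
    fused across windows, so every group attends to a fixed number of keys that
    carry image-wide, multi-scale context. Includes the hierarchical
    encoder-decoder with overlapping patch embedding, patch merging/expanding,
    a multi-stage transformer context bridge, a hybrid dice + cross-entropy
    loss, Dice and Hausdorff evaluation metrics, a deterministic multi-class
    phantom generator, a compact reverse-mode automatic-differentiation engine
    that powers SGD training on CPU, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    png,
    RNifti,
    yaml,
    EBImage,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
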