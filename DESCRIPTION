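Package: histopatch
Title: Multispace Image Reconstruction and Patch-Based Classification of
    H&E Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A patch-based classification pipeline for hematoxylin and
    eosin stained micrographs. Whole images are rebuilt as three-channel
    "multispace" images whose channels are Sobel gradient, sliding-window
    gray-level cooccurrence matrix (GLCM) statistic, and local binary
    pattern (LBP) maps of the white-balanced grayscale image. A VGG-16
    style convolutional backbone maps each non-overlapping 64x64 patch of
    the RGB and reconstructed images to 2048-dimensional features; a
    dual-stream LSTM compresses each stream to 32 dimensions and a fused
    64-dimensional cascade drives a softmax classifier trained with a
    combined per-stream cross-entropy loss. Image labels are obtained by
    majority vote over patch predictions, evaluated with accuracy and
    per-class sensitivity/specificity under image-level k-fold
    cross-validation. A seeded generator of H&E-like synthetic images and
    feature fixtures makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
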