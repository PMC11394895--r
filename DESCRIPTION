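Package: peppersort
Title: Multi-Domain Feature Fusion Networks and Flat-Region Sorting for
    Peppercorn Maturity Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for grading fresh Sichuan peppercorn imagery by maturity
    and color uniformity. Implements multi-scale frequency-domain feature
    fusion layers (FFT magnitude/phase strip-convolution attention), a
    dual-domain squeeze-and-excitation plus multi-scale spatial attention
    layer, deep Fourier up-sampling by periodic spectrum tiling, assembly of
    YOLOv8-style segmentation and classification networks from these blocks
    with a reverse-mode autograd engine and SGD training, the average
    local-pixel-value-difference flat-region sorter for selecting
    high-quality granules, detection/classification evaluation metrics
    (precision, recall, mAP50, GFLOPs, FPS), YOLO polygon label I/O, and
    deterministic synthetic cluster-scene fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
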