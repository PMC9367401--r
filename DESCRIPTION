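Package: contourseg
Title: Contour-Based Instance Segmentation with a Few-Shot Detector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, two-stage contour-based instance segmentation
    pipeline for animal imagery. Stage one is a few-shot object detector
    (base training on abundant classes, then box-predictor-only fine-tuning
    on n-shot subsets with a frozen feature extractor). Stage two is a
    learning-based active-contour ("deep snake") deformer: the detector box
    is turned into a diamond contour, a circular-convolution network predicts
    the four extreme points, an octagon is built from them, and iterative
    per-vertex offset regression shrinks the octagon onto the object
    boundary. Includes a seeded synthetic scene generator with COCO-format
    ground truth emulating camera-trap challenge regimes, and COCO-style
    AP/AP50/AP75 evaluation for both boxes and masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
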