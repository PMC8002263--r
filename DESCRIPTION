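Package: chfnet
Title: Congestive Heart Failure Detection from Short RR-Interval Segments
    with a 1-D UNet++
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects congestive heart failure (CHF) from short segments of
    RR intervals (the beat-to-beat tachogram) using a one-dimensional UNet++
    encoder-decoder with squeeze-and-excitation residual convolution blocks.
    Provides the full pipeline: beat-annotation-based RR cleaning (ectopic
    and long-pause removal), fixed-length segmentation with zero padding,
    the nested-skip network with plain-residual and inception block variants,
    subject-wise k-fold cross-validation with an Adam / plateau learning-rate
    protocol, confusion-matrix and ROC/AUC reporting, and a seeded synthetic
    RR-cohort generator so every stage runs without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
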