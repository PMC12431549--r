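Package: ecgcnn
Title: Lightweight 1D Convolutional Networks for Single-Lead ECG Arrhythmia Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for detecting cardiac
    arrhythmias in single-lead 128 Hz electrocardiograms of the kind recorded
    by smartwatches and Holter monitors. Provides WFDB-style record input and
    output, a five-stage preprocessing chain (Butterworth baseline removal,
    level-dependent sym4 wavelet denoising, per-window z-scoring, fixed
    1000-sample windowing, one-hot class coding), declarative 1D convolutional
    network architectures with analytic shape propagation and parameter and
    FLOP accounting, a self-contained training engine with patient-wise
    (grouped holdout and leave-one-subject-out) evaluation, class-balancing
    resampling, a full metric suite with bootstrap confidence intervals,
    1D Grad-CAM saliency maps, and a seeded synthetic ECG cohort generator so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
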