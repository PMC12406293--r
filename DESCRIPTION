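Package: cineRT
Title: Retrospective Synchronization of Real-Time Cardiac MRI Cines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constructs retrospectively synchronized, time-resolved
    ventricular cine images from multi-heartbeat 2D real-time cardiac
    magnetic resonance acquisitions, as used in free-breathing and
    exercise imaging where ECG gating and breath-holds are unavailable.
    Provides image-based respiratory gating from a diaphragm region of
    interest via a one-dimensional spectral embedding, rule-based
    detection of end-diastolic and end-systolic timeframes from left
    ventricular area curves, cross-slice synchronization by separate
    temporal resampling of systolic and diastolic intervals, slice
    summation left ventricular volumetry and mass, and Bland-Altman
    agreement statistics. A digital cardiorespiratory phantom with known
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
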