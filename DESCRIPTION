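Package: erpshape
Title: Shape-Domain P300 Detection with Slope Horizontal Chain Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects P300 event-related potentials in epoched EEG by their
    waveform shape. Curves are encoded with a Slope Horizontal Chain Code
    (SHCC): the epoch is resampled to S straight-line segments, min-max
    normalized to the unit square, and each segment's inclination is
    quantized to a two-decimal symbol. Chains support an l1 distance and a
    tortuosity measure; together with trapezoid-rule segment-area
    differences they form a (2S+2)-dimensional shape-feature vector. A
    wrapper-based calibration algorithm builds per-subject P300 templates
    by coherent averaging, scores electrodes by cross-validated AUROC,
    reduces features by p-value-driven stepwise regression, and selects
    electrodes, templates and the optimum number of stimulations.
    Stepwise linear discriminant analysis and linear support-vector
    classifiers plus a validation harness complete the pipeline. A
    built-in oddball-paradigm ERP simulator generates labeled epoch sets
    for end-to-end testing without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
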