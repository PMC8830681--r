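Package: circaphage
Title: Circadian Analysis of Amyloid-Beta Phagocytosis and Proteoglycan Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies per-cell fluorescence from microscopy images of
    macrophages phagocytosing labelled amyloid-beta, preprocesses the
    intensities (background thresholding, log10 transform, interquartile-range
    outlier removal), fits an extended-harmonic-oscillator (damped cosine)
    model to replicate-resolved time series to classify circadian
    rhythmicity with Benjamini-Hochberg and Benjamini-Yekutieli gates,
    runs joint Welch/Hedges two-group inference, and normalizes heparan and
    chondroitin sulfate disaccharide concentrations to per-cell units via a
    fluorescence standard curve. Includes a seeded synthetic-data generator
    for every input the pipeline consumes, with ground truth retained for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
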