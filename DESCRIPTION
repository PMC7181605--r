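Package: fibroquant
Title: Morphometric Quantification of Renal Interstitial Fibrosis from
    Sirius-Red Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies interstitial fibrosis on Sirius-Red stained renal
    cortex sections as the percent of positively stained area (mIF), using a
    per-slide two-class Gaussian colour model calibrated from operator-drawn
    positive and negative reference patches so that results are comparable
    across staining batches. Includes polygon annotation I/O (GeoJSON),
    mask rasterization, a deterministic synthetic-histology generator with
    ground-truth fibrosis masks, the validation statistics used for such
    morphometry (one-way random-effects intraclass correlation with F-based
    confidence intervals, Fisher-z Pearson intervals, paired location tests,
    simple least-squares associations), and a longitudinal biopsy-cohort
    simulator and analysis for fibrosis progression after transplantation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
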