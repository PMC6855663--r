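Package: radiosynergy
Title: Growth, Survival, Dosimetry and Histology Analysis for
    Radiation-Chemotherapy Combination Studies in Tumour Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing preclinical combination-therapy studies in
    tumour-bearing mice: calliper-based tumour volumes and relative tumour
    volumes (RTV), Kaplan-Meier progression-free survival with a
    nadir-aware progression rule, mean absorbed dose from time-activity
    data via the MIRD formalism, Bliss-independence interaction scoring of
    radiation-drug combinations, per-day group statistics with
    Bonferroni-Holm correction, and quantitative immunohistochemistry of
    Masson's trichrome / Ki67 section pairs (colour-threshold segmentation,
    necrosis detection, control-point registration, positive-area
    fractions). A synthetic-data module generates cohorts, tracer kinetics
    and stained-section image pairs with known ground truth so every
    pipeline stage is testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    mgcv,
    png,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    survival,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
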