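Package: cd8pheno
Title: Spatial CD8+ T-Cell Density Scoring and Immune Phenotyping of
    Chromogenic IHC Slides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A standardized digital-pathology workflow that quantifies
    spatial densities of CD8+ tumor-infiltrating T cells in chromogenic
    immunohistochemistry slides of metastatic melanoma and translates them
    into the immune diagnoses "desert", "excluded" and "inflamed". The
    pipeline covers optical-density stain deconvolution (hematoxylin
    counterstain, Alkaline-Phosphatase red chromogen), patch-based
    six-class tissue classification, seeded-watershed nucleus detection
    with morphometric filtering and marker scoring, tumor-compartment
    geometry (intratumoral and stromal tumor center, invasive margin),
    density cut-off derivation and per-class diagnostic-accuracy
    evaluation. A synthetic slide generator with exact per-cell ground
    truth makes every stage testable without clinical material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
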