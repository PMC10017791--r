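Package: mpmtex
Title: Texture-Based Classification of Multiphoton Microscopy Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated discrimination of tumor versus normal tissue
    in three-channel label-free multiphoton microscopy (CARS, TPEF, SHG)
    field-of-view images. Provides tile quality control, per-channel
    first-order and gray-level co-occurrence matrix (GLCM) texture features
    with orientation averaging, linear and quadratic discriminant
    classification with posterior probabilities, patient-aware train/test
    splitting and leave-one-sample-out cross-validation, tiled
    posterior-probability maps, and a seeded synthetic two-class cohort
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
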