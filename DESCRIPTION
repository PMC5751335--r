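Package: qsar3d
Title: Molecular-Field 3D-QSAR with PLS Cross-Validation and External
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative molecular field analysis (CoMFA) and comparative
    molecular similarity indices analysis (CoMSIA) for sets of rigidly
    aligned 3D structures, coupled to partial least squares (PLS)
    regression with leave-one-out cross-validation, exhaustive
    field-combination model search, and the standard external-validation
    battery for QSAR models (predictive r-squared, rm-squared and the
    Golbraikh-Tropsha criteria).  Includes Gasteiger partial-charge
    assignment, Kabsch core superposition, contour-map extraction from
    fitted models, and a synthetic-molecule generator with a planted
    field-activity relationship for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
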