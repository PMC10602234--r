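Package: sabscreen
Title: PCA-Based Screening of HLA Single Antigen Bead Antibody Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens Luminex HLA single antigen bead (SAB) antibody results for
    clinically relevant deviations from a patient's historic reactivity
    pattern. Per-patient principal component analysis of normalized MFI values
    yields a Euclidean distance ratio in PC1/PC2 score space; samples at or
    above a ROC-calibrated threshold (default 1.4) are flagged for manual
    review. A transposed PCA across low-reactivity sera ranks single antigen
    beads by their distance ratio to identify over-reactive beads. Includes
    CSV import/export for wide and long MFI tables, ROC threshold calibration
    with Youden's J, rank-based cohort comparison tests, and a seeded
    synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
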