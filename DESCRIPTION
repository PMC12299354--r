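Package: dyskrep
Title: Movement-Data Representations for Wrist-Accelerometer Dyskinesia Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares movement-data representations for detecting levodopa-induced
    dyskinesia from wrist-worn tri-axial accelerometer recordings of the alternating
    pronation-supination task (UPDRS 3.6). Implements a semantic representation
    (per-session principal-component projection, extremum-based segmentation into
    beginning/middle/end parts, and a catalogue of nine biomechanical feature kinds),
    an automatic time-series feature catalogue with statistical relevance filtering,
    a grid-search model-selection harness (stratified cross-validation, SMOTE
    oversampling, ANOVA-F feature selection, five classifier families, macro-F1
    ranking), and a cross-cohort transfer evaluation. Includes a synthetic
    pronation-supination signal simulator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    ranger,
    xgboost,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
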