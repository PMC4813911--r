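Package: qsaeeg
Title: Quaternion-Based Signal Analysis for EEG Motor-Imagery Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models multichannel electroencephalographic (EEG) signals as
    quaternion time series and extracts Haralick-style statistical features
    from the modulus of a lagged quaternion rotation (quaternion-based
    signal analysis, QSA). Includes a seeded simulator of cue-based
    motor-imagery sessions with lateralized event-related desynchronization,
    CSV session input/output, segmentation on class changes, and a
    training/validation harness over decision trees, k-nearest neighbours
    and one-vs-rest RBF support vector machines with per-class
    sensitivity/specificity/likelihood performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    class,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
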