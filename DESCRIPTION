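Package: osteosex
Title: Osteometric Sex Estimation from the Postcranial Skeleton
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Metric sex estimation from postcranial skeletal measurements.
    Applies published Italian univariate sectioning points and multivariable
    logistic regression standards to measurement records, including
    fragmentary and commingled remains, and reproduces the full
    standards-development pipeline on any osteometric dataset: technical
    error of measurement (TEM, rTEM, R) reliability analysis, sexual
    dimorphism screening, sectioning-point derivation, bone-wise logistic
    model fitting, and train/test validation with per-sex accuracies and
    class discrimination bias. A synthetic-data generator emulates the
    per-sex measurement distributions of a reference skeletal collection so
    that every pipeline stage can be exercised without access to the
    original remains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
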