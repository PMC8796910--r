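Package: pikaDemog
Title: Life-History Demography of the Plateau Pika from Mark-Recapture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort (dynamic) life tables, a triple-catch mark-recapture
    survival estimator, age-specific fertility and Fisherian reproductive
    value, a composite fitness index for comparative mammalian vital-rates
    tables, Charnov dimensionless life-history invariants, an ontogenetic
    growth model with quarter-power anabolism, and a Burnham-Overton
    jackknife abundance estimator for heterogeneous capture (model Mh).
    Includes an individual-based mark-recapture simulator so every stage of
    the pipeline can be exercised and validated on synthetic populations,
    and published plateau pika (Ochotona curzoniae) demographic tables as
    packaged delimited-text data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
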