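Package: catrace
Title: Stimulus-Response Calcium Imaging Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of evoked calcium transients in Fluo-4 timelapse
    recordings of iPSC-derived cultures. Provides a SummarizedExperiment-based
    container for per-cell fluorescence traces under a fixed stimulation
    protocol (receptor agonist, ionomycin, EGTA), background subtraction and
    baseline fold-change normalization, per-cell kinetic feature extraction
    (window maxima, time-to-peak, responder classification), pooled
    ASD-versus-control group comparison with the two-tailed Mann-Whitney U
    test, a calibrated synthetic-cohort generator for parameter-recovery
    validation, and a differentiation-stage screen over differentially
    expressed genes using hypergeometric gene-set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
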