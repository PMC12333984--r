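Package: radiomiR
Title: Prognostic Plasma miRNA Signatures from RT-qPCR Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of circulating microRNA RT-qPCR panels for
    dose-group discrimination and injury prognosis: hemolysis and spike-in
    quality control, adaptive (-)delta-Ct normalization with data-driven
    reference selection by Ward clustering, sparse multiblock partial least
    squares discriminant analysis (DIABLO-style) with leave-one-out tuning
    and stability selection, one-vs-rest ROC evaluation, and a Bayesian
    latent-variable bridge correlating signature components with clinical
    outcomes measured on independent cohorts. Includes a seeded synthetic
    cohort generator with planted ground truth for recovery and calibration
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: qPCR, Normalization, Classification, DimensionReduction,
    Bayesian, QualityControl
RoxygenNote: 7.3.3
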