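Package: cavemet
Title: Untargeted Metabolomics Differential Abundance for Cave and Surface Fish
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable implementation of an untargeted metabolomics
    analysis pipeline for comparing cave-adapted and surface populations of
    Astyanax mexicanus across tissues and feeding states. Provides mTIC
    (identified-peak total ion current) normalization, within-comparison
    log10 z-scoring, O-PLS orthogonal signal correction, one-component
    PLS classification scored by cross-validated Q2 and truncated DQ2 with
    permutation significance, per-feature Bayesian logistic regression with
    Cauchy priors that remains finite under complete separation, and a
    parallel-adaptation contrast test (Pachon + Tinaja)/2 - Surface. A
    synthetic metabolome generator with planted effects and ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    nortest,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Metabolomics, Lipidomics, Normalization, Classification,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
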