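Package: AbetaMM
Title: Multimodal EEG and MRI Prediction of the CSF Amyloid-Beta 42/40 Ratio
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the cerebrospinal-fluid amyloid-beta 1-42/1-40
    concentration ratio, the biochemical gold standard for amyloid
    positivity, from noninvasive multimodal data: resting-state EEG
    features (segment-averaged band energies, normalized Lempel-Ziv
    complexity, histogram mutual information between brain regions, and
    windowed standard-deviation microstates), linear ventricular atrophy
    indices measured on structural MRI, visual atrophy grades, and
    cognitive scale scores. Provides a seeded synthetic-cohort generator
    that plants the group-level effect structure reported for clinical
    amyloid cohorts, group statistics, and a leakage-free random-forest
    cross-validation stage with correlation-ranked feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    randomForest,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'montage.R'
    'edf.R'
    'brainvision.R'
    'core_data.R'
    'mri.R'
    'statistics.R'
    'spectral.R'
    'complexity.R'
    'microstates.R'
    'synthetic.R'
    'extract.R'
    'regressor.R'
    'pipeline.R'
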