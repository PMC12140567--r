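Package: multiplexSCN
Title: Dual-Layer Multiplex Structural Covariance Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction and group comparison of dual-layer multiplex
    brain networks built from region-of-interest cortical thickness and
    FDG-PET SUVR tables. Covariate residualization (age, sex, education),
    group-level Pearson correlation layers, density or absolute-value
    thresholding across a sweep, supra-adjacency assembly with replica
    coupling, multiplex graph measures (intralayer degree, overlapping
    degree, nodal and global multiplex participation coefficient),
    nonparametric permutation inference with Benjamini-Hochberg FDR
    control, demographic cohort statistics, and a synthetic multimodal
    cohort generator with plantable layer-imbalanced correlation effects
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Neuroimaging, StatisticalMethod
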