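Package: covnet
Title: Brain Metabolic Covariance Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Group-level metabolic covariance network analysis for regional
    FDG-PET standardized uptake value ratio (SUVR) tables. Builds per-group
    inter-subject Pearson covariance networks, assigns edge-level significance
    with a random-shift permutation null, thresholds networks, computes signed
    global and nodal graph measures and hub regions, detects community
    structure by signed-modularity Louvain optimization with multiresolution
    consensus clustering, and compares groups with Kolmogorov-Smirnov tests,
    edgewise group-label permutation tests with FDR control, and factorial
    ANOVA of module-mean SUVR with Tukey-Kramer post hoc tests. Includes a
    seeded synthetic-cohort generator with planted modular covariance
    structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'covnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'accessors.R'
    'metrics.R'
    'network.R'
    'comparison.R'
    'io.R'
    'louvain.R'
    'module-stats.R'
    'mrcc.R'
    'partition-similarity.R'
    'pipeline.R'
    'simulate.R'
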