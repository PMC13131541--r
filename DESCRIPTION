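Package: onecarbon
Title: B-Vitamin and One-Carbon Metabolism Association Analysis for Post-Mortem Brain Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for targeted-metabolomics and SNP association
    analysis of B-vitamin-related compounds in post-mortem brain tissue.
    Provides synthetic cohort, assay-plate and genotype simulators with planted
    effects and linkage disequilibrium; plate-level preprocessing (quadratic
    calibration, blank-based limits of detection, group-respecting plate
    normalization, Box-Cox transformation, Tukey fencing, control-based
    standardization); multivariable linear regression with group-specific
    residual variance fitted by maximum likelihood; Wilcoxon-Mann-Whitney SNP
    scans with inheritance-model selection by BIC and two-locus linkage
    disequilibrium statistics; composite genetic and metabolic burden scores;
    and a genetic-programming expression-tree classifier for combinatorial
    subgroup discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    car,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
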