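Package: grsInteract
Title: Genetic Risk Score by Environment Interaction Analysis with
    Distribution-Matched Negative Controls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for testing interactions between a weighted genetic risk
    score (GRS) and environmental exposures on a quantitative outcome, with
    an emphasis on distinguishing genuine gene-environment interaction from
    artefacts of differing outcome distributions between exposure groups.
    Implements weighted GRS construction from per-variant dosages and
    discovery weights, rank-based inverse normal transformation of the
    outcome, stratified and interaction linear models (including the Keller
    covariate-interaction sensitivity analysis), per-variant interaction
    scans, genetic-risk decile contrasts, and a negative-control engine that
    repeatedly selects disjoint pseudo-exposure groups matched to the
    observed groups' outcome mean and standard deviation to build an
    empirical null distribution for the interaction P-value. A
    synthetic-cohort generator emulates the assumed data structure
    (GRS-linked BMI, exposure groups with shifted and rescaled outcome
    distributions, optional multiplicative noise) so the full pipeline is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Regression,
    GeneticVariability
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
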