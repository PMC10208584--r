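Package: ptbomics
Title: Multiomic and Epidemiological Modeling of Preterm Birth Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for multi-site preterm-birth cohort studies
    combining an epidemiological covariate table with plasma proteomic,
    metabolomic, and lipidomic profiling. Provides a synthetic cohort
    generator with planted, recoverable signal structure; readers, validators
    and mean imputation for cohort and omics tables; an all-pairs Spearman
    interactome with an analytic Bonferroni-derived correlation threshold,
    strength binning, per-omic-pair normalization and a bootstrap null;
    a repeated split-half cross-validation harness around gradient-boosted
    trees with per-participant prediction averaging and prevalence-aware
    evaluation (AUROC, AUPRC, Lift, per-site metrics); stability-based
    minimal-panel feature selection; gestational-clock discrepancy analysis;
    and a minimum-spanning-tree covariate correlation network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Metabolomics, Lipidomics, Epidemiology,
    MachineLearning, Network
RoxygenNote: 7.3.3
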