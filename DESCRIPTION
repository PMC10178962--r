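Package: riskpanel
Title: Exhaustive Gene-Panel Discovery and Linear-Discriminant Risk
    Scoring for Treatment-Resistance Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers and validates gene-expression risk panels that
    separate pre-treatment from progressed/resistant tumour biopsies.
    Implements exhaustive enumeration of gene subsets scored by linear
    discriminant analysis and ROC AUC, a per-sample linear risk score with
    patient-level fold-change stratification, per-gene association
    statistics (logistic odds ratios, Kruskal-Wallis tests, Spearman
    correlation modules, PCA contributions), z-score merging of
    multi-cohort expression data, hypergeometric pathway
    over-representation with single-sample pathway activity scores, and a
    seeded synthetic-cohort generator so the whole pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    cluster,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
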