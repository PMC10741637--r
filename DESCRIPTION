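Package: EVproteomics
Title: Differential Proteomics of Cerebrospinal-Fluid Extracellular Vesicle Fractions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for label-free proteomic comparison of unprocessed
    cerebrospinal fluid against its microvesicle and exosome fractions:
    presence filtering, left-censored (downshifted-normal) imputation,
    quantile normalisation, sample QC by multidimensional scaling with
    k-means, per-protein ANOVA and pairwise Welch tests with
    Benjamini-Hochberg correction and post-hoc power gating, hyperbolic
    volcano cutoffs, PLS-DA variable importance and linear-SVM recursive
    feature elimination for biomarker panel construction, rank-based
    two-dimensional annotation enrichment, kinase enrichment analysis, and
    ELISA validation statistics (plate reduction, Kruskal-Wallis, ROC with
    DeLong intervals, Youden cutoff and likelihood ratios). A seeded
    simulator generates three-fraction proteomes, annotation sets and ELISA
    cohorts with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    e1071,
    mclust,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
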