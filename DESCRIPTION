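Package: miRResponse
Title: Circulating miRNA Biomarker Discovery and SVM-Based Drug Response
    Prediction from Paired miRNA/mRNA Expression Profiles
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for nominating circulating miRNA
    biomarkers of drug response from paired miRNA/mRNA expression profiles
    of responder and non-responder cohorts, and for predicting responder
    status with a radial-basis-function support vector machine.  Stages:
    random-variance-model moderated t-test screening with fold-change and
    Benjamini-Hochberg FDR gates and hierarchical clustering; intersection
    of two miRNA target-prediction tables; an anti-correlation miRNA-target
    co-expression network with degree-based key-miRNA ranking; a
    median-score-filtered gene-gene interaction network with degree,
    betweenness and closeness centralities, strict above-median hub calls,
    Markov clustering into functional modules, hypergeometric module
    enrichment and edge-betweenness key-interaction ranking; biomarker
    panel assembly from the most significantly dysregulated upstream
    miRNAs of the key-interaction genes; and repeated stratified k-fold
    cross-validation of the RBF-kernel SVM with ROC/AUC analysis, DeLong
    AUC comparisons and a comparative-CT qPCR fold-change helper.  A
    synthetic two-group cohort generator with planted ground truth makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    e1071,
    pROC,
    ape,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
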