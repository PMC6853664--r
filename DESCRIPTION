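Package: ternadex
Type: Package
Title: Ternary Discretization of Time-Course Differential Expression with
    SDE Ensemble Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hybrid analysis of time-course differential gene
    expression. Gene-wise linear models with empirical-Bayes variance
    moderation yield moderated contrasts across five contrast families
    (pairwise, time-series, autoregressive and their condition-differenced
    forms), which are discretized into ternary response profiles and used to
    classify genes as differentially expressed, dynamically differentially
    expressed or differentially responding. A combinatorial library of
    three-node stochastic differential equation models (perturbed gene,
    rest-of-genome proxy, gene of interest) is enumerated, simulated under
    wild-type, knockout, knockin and inhibition conditions, and matched to
    genes by identical discrete profiles; matched ensembles predict
    expression under untested perturbations via per-time median log
    fold changes, with scoring against a random-model null, ranking,
    and gene-set / ontology enrichment on discrete-response clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    deSolve,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: TimeCourse, DifferentialExpression, NetworkInference,
    GeneRegulation, Software
RoxygenNote: 7.3.3
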