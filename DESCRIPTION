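Package: gwfp
Title: Genome-Wide Family Prediction for Pooled Half-Sib Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Genomic prediction of agronomic traits at the family level from
    pool genotyping-by-sequencing data. Families are genotyped as alternative
    allele read fractions, filtered and imputed into an allele-frequency
    matrix, and phenotypes are predicted with six regression engines (RKHS
    with a Gaussian kernel and Bayesian ridge regression fitted by Gibbs
    sampling, plus support vector machines, random forests, adaptive boosting
    and a multilayer perceptron) under repeated k-fold cross-validation.
    Tree-ensemble feature selection with intersection sets and Gini
    importance identifies major markers, which are linked to annotated genes
    by physical windows and expanded through a highest-reciprocal-rank gene
    coexpression network with seasonal subnetworks, hub detection and
    hypergeometric term enrichment. A synthetic-data generator emulates the
    pooled half-sib design end to end for testing and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    xgboost,
    e1071,
    rpart,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
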