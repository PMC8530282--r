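Package: isomapnet
Title: Isoform-Aware Neural Network Models for RNA-Seq Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds splice-aware predictive models from RNA-seq count data.
    Transcript annotation is flattened into disjoint exonic parts and binary
    exon-to-isoform and exon-to-gene relationship matrices, which constrain
    the weights of Isoform Map and Gene Map neural-network layers; a
    non-negative L1-penalised Feature Selection Layer provides built-in
    importance scores. Includes the accompanying preprocessing pipeline
    (CPM filtering, TMM or upper-quartile normalisation, log2-CPM, quantile
    normalisation, covariate adjustment), stratified data splitting with
    5-fold cross-validation, Adam training with early stopping, greedy
    layer-by-layer architecture search, logistic-regression and elastic-net
    baselines, ROC/AUC evaluation with the DeLong paired test, saliency-map
    interpretation, and a negative-binomial isoform-switch simulator for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    limma,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pROC,
    glmnet
Config/testthat/edition: 3
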