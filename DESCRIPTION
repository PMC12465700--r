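Package: wmkrr
Title: Weighted Multiple-Kernel Ridge Regression for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction by kernel ridge regression on a weighted
    combination of a genotype-derived kernel and a (genetically predicted)
    gene-expression kernel, with kernel weight, ridge penalty and Gaussian
    bandwidth tuned by Bayesian optimization (Gaussian-process surrogate,
    expected-improvement acquisition, inner cross-validated Pearson
    correlation objective).  Includes GBLUP and GTBLUP baselines fitted by
    average-information REML with EM fallback, VanRaden genomic and
    gene-expression relationship matrices, cis-heritability estimation,
    univariate SNP feature selection, an elastic-net predictor of
    cis-regulated gene expression, a QTL phenotype simulator with full
    ground-truth export, and cross-validation / forward-validation
    evaluation with predictive ability, unbiasedness and centered RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
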