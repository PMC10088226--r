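Package: tradervote
Title: Trader Wrapper Feature Selection and Voting-Based Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Wrapper feature selection for biomedical tabular data using the
    population-based Trader metaheuristic (retailing, distributing and
    importing-exporting operators over grouped candidate feature subsets,
    scored by cross-validated SVM accuracy), together with a majority-voting
    ensemble classifier, correlation-based missing-value imputation, min-max
    normalization, a synthetic dataset generator with known informative
    features, and an evaluation harness (stratified cross-validation,
    mean-based multiclass metrics, one-vs-rest ROC/PR curves with AUC,
    Wilcoxon rank-sum run comparison, convergence and stability summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
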