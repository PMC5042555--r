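Package: litclass
Title: TF-IDF Text Classification for Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single-machine pipeline for classifying biomedical abstracts
    and articles into predefined categories. Reads MEDLINE flat files and
    simple labeled corpora (JSONL/CSV), normalizes and tokenizes text,
    removes stop-words, applies Porter stemming, builds unigram and bigram
    vocabularies with document frequencies, and converts documents into
    equal-length sparse TF-IDF feature vectors. Ships three classifiers
    trained from their primal formulations -- multinomial naive Bayes with
    Laplace smoothing, linear SVM (hinge loss) and logistic regression via
    regularized subgradient descent (none/L1/L2) -- with one-vs-rest
    multiclass reduction, repeated stratified k-fold cross-validation,
    confusion-matrix metrics and ROC/AUC analysis, plus a seeded synthetic
    corpus generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pROC,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
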