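#' Train an end-to-end text classifier on a labeled corpus
#'
#' Runs the full pipeline: preprocessing (normalize, tokenize, stop-words,
#' Porter stemming), unigram/bigram vocabulary with rare-word filtering,
#' TF-IDF vectorization, then one of three classifiers — multinomial naive
#' Bayes (native multiclass), linear SVM or logistic regression (one-vs-rest).
#' The vocabulary and IDF come from the training corpus only; at prediction
#' time terms unseen in training are dropped.
#'
#' @param x a labeled [corpus()]; every document must have a label.
#' @param classifier `"nb"`, `"svm"` or `"logreg"`.
#' @param ngram_orders n-gram orders (default unigrams + bigrams).
#' @param min_df rare-word filter: minimum document frequency (default 2).
#' @param stopwords stop-word vector (default: bundled English list).
#' @param collapse_repeats see [preprocess_document()].
#' @param config a [train_config()] (linear classifiers; `lambda` for NB).
#' @return object of class `text_classifier`.
#' @export
train_text_classifier <- function(x, classifier = c("nb", "svm", "logreg"),
                                  ngram_orders = c(1L, 2L), min_df = 2L,
                                  stopwords = load_stopwords(),
                                  collapse_repeats = FALSE,
                                  config = train_config()) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(x, "corpus"))
  if (anyNA(x$label)) stop("every document must be labeled", call. = FALSE)
  tokens <- preprocess_corpus(x, stopwords, collapse_repeats)
  .fit_on_tokens(tokens, x$label, classifier, ngram_orders, min_df,
                 stopwords, collapse_repeats, config)
}

# fit from cached token sequences (shared with cross_validate)
.fit_on_tokens <- function(tokens, labels, classifier, ngram_orders, min_df,
                           stopwords, collapse_repeats, config) {
  vocab <- build_vocabulary(tokens, orders = ngram_orders, min_df = min_df)
  X <- vectorize_corpus(tokens, vocab)
  model <- switch(classifier,
    nb = train_naive_bayes(X, labels, lambda = config$lambda),
    svm = ovr_train(X, labels, loss = "hinge", config = config),
    logreg = ovr_train(X, labels, loss = "logistic", config = config)
  )
  structure(list(classifier = classifier, vocab = vocab, model = model,
                 ngram_orders = ngram_orders, min_df = min_df,
                 stopwords = stopwords, collapse_repeats = collapse_repeats,
                 config = config,
                 classes = model$classes),
            class = "text_classifier")
}

#' @export
print.text_classifier <- function(x, ...) {
  cat(sprintf("<text_classifier> %s; %d classes (%s); %d features\n",
              switch(x$classifier, nb = "naive Bayes",
                     svm = "linear SVM (hinge)", logreg = "logistic regression"),
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$vocab$terms)))
  invisible(x)
}

#' Predict classes for new documents
#'
#' @param object a [train_text_classifier()] model.
#' @param newdata a [corpus()] (labels, if any, are ignored).
#' @param ... unused.
#' @return data.frame with `doc_id`, `label` (predicted) and one score column
#'   per class (posterior probabilities for NB, decision scores for the
#'   linear models).
#' @export
predict.text_classifier <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "corpus"))
  tokens <- preprocess_corpus(newdata, object$stopwords,
                              object$collapse_repeats)
  X <- vectorize_corpus(tokens, object$vocab)
  if (object$classifier == "nb") {
    pred <- nb_predict(object$model, X)
    scores <- pred$posterior
  } else {
    pred <- ovr_predict(object$model, X)
    scores <- pred$scores
  }
  out <- data.frame(doc_id = newdata$doc_id, label = pred$label,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' For each of `repeats` seeded repetitions the corpus is partitioned into
#' `k` folds (stratified by class by default); each fold in turn is held out
#' for testing while the vocabulary, IDF and classifier are rebuilt on the
#' remaining folds. Reported metrics are overall accuracy and macro-averaged
#' precision and recall on the held-out fold; the grand mean over all
#' `k * repeats` folds is the headline number.
#'
#' @param x a labeled [corpus()]; every class needs at least `k` members.
#' @param classifier `"nb"`, `"svm"` or `"logreg"`.
#' @param k folds per repetition (default 5).
#' @param repeats number of repetitions (default 10); repetition `r` uses
#'   seed `seed + r - 1`.
#' @param seed base integer seed.
#' @param stratified stratify folds by class? Default `TRUE`.
#' @inheritParams train_text_classifier
#' @return object of class `cv_result`: data.frame `folds` (columns `rep`,
#'   `fold`, `accuracy`, `precision`, `recall`), `mean_accuracy`,
#'   `sd_accuracy`, and the protocol parameters.
#' @export
cross_validate <- function(x, classifier = c("nb", "svm", "logreg"),
                           k = 5L, repeats = 10L, seed = 1L,
                           stratified = TRUE,
                           ngram_orders = c(1L, 2L), min_df = 2L,
                           stopwords = load_stopwords(),
                           collapse_repeats = FALSE,
                           config = train_config()) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(x, "corpus"))
  if (anyNA(x$label)) stop("every document must be labeled", call. = FALSE)
  counts <- table(x$label)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop("class '", small[1L], "' has fewer than k = ", k, " members",
         call. = FALSE)
  }
  tokens <- preprocess_corpus(x, stopwords, collapse_repeats)
  labels <- x$label
  n <- nrow(x)
  rows <- vector("list", k * repeats)
  seeds <- seed + seq_len(repeats) - 1L
  for (r in seq_len(repeats)) {
    folds <- if (stratified) {
      stratified_kfold_indices(labels, k, seeds[r])
    } else {
      kfold_indices(n, k, seeds[r])
    }
    stopifnot(length(unique(unlist(folds))) == n)  # partition law
    for (f in seq_len(k)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      stopifnot(length(intersect(train_idx, test_idx)) == 0L)
      fit <- .fit_on_tokens(tokens[train_idx], labels[train_idx], classifier,
                            ngram_orders, min_df, stopwords, collapse_repeats,
                            config)
      X_test <- vectorize_corpus(tokens[test_idx], fit$vocab)
      pred <- if (classifier == "nb") {
        nb_predict(fit$model, X_test)$label
      } else {
        ovr_predict(fit$model, X_test)$label
      }
      m <- multiclass_metrics(labels[test_idx], pred)
      rows[[(r - 1L) * k + f]] <- data.frame(
        rep = r, fold = f, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall
      )
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df,
                 mean_accuracy = mean(folds_df$accuracy),
                 sd_accuracy = stats::sd(folds_df$accuracy),
                 mean_precision = mean(folds_df$precision),
                 mean_recall = mean(folds_df$recall),
                 classifier = classifier, k = k, repeats = repeats,
                 seeds = seeds, stratified = stratified),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: %d x %d-fold CV\n  mean accuracy %.4f (sd %.4f), macro precision %.4f, macro recall %.4f\n",
    x$classifier, x$repeats, x$k, x$mean_accuracy, x$sd_accuracy,
    x$mean_precision, x$mean_recall))
  invisible(x)
}

# ---- model serialization ----------------------------------------------------

#' Save / load a trained text classifier as JSON
#'
#' The container stores a schema version, the preprocessing settings
#' (including the stop-word list), the vocabulary with document frequencies,
#' the class labels and the model tables (dense weight vectors per class for
#' the linear models; log-probability tables for naive Bayes), so a saved
#' model predicts identically after a round-trip.
#'
#' @param object a `text_classifier`.
#' @param path file path for the JSON model.
#' @return `path` invisibly (writer); a `text_classifier` (reader).
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "text_classifier"))
  m <- object$model
  model_block <- if (object$classifier == "nb") {
    list(type = "nb", classes = m$classes, log_prior = unname(m$log_prior),
         log_lik = unname(as.matrix(m$log_lik)), lambda = m$lambda)
  } else {
    list(type = "ovr", classes = m$classes, loss = m$loss,
         weights = lapply(m$models, function(mm) unname(mm$w)),
         regularizer = m$models[[1L]]$regularizer,
         reg_param = m$models[[1L]]$reg_param)
  }
  payload <- list(
    schema_version = 1L,
    classifier = object$classifier,
    ngram_orders = object$ngram_orders,
    min_df = object$min_df,
    collapse_repeats = object$collapse_repeats,
    stopwords = object$stopwords,
    vocabulary = list(terms = object$vocab$terms, df = object$vocab$df,
                      n_docs = object$vocab$n_docs),
    config = unclass(object$config),
    model = model_block
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != 1L) {
    stop("unsupported model schema", call. = FALSE)
  }
  vocab <- structure(list(terms = p$vocabulary$terms,
                          df = as.integer(p$vocabulary$df),
                          n_docs = as.integer(p$vocabulary$n_docs),
                          orders = as.integer(p$ngram_orders),
                          min_df = as.integer(p$min_df)),
                     class = "vocabulary")
  cfg <- do.call(train_config, p$config)
  d <- length(vocab$terms)
  model <- if (p$model$type == "nb") {
    ll <- p$model$log_lik
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = length(p$model$classes))
    rownames(ll) <- p$model$classes
    structure(list(classes = p$model$classes,
                   log_prior = stats::setNames(p$model$log_prior,
                                               p$model$classes),
                   log_lik = ll, lambda = p$model$lambda, d = d),
              class = "nb_model")
  } else {
    classes <- p$model$classes
    models <- lapply(classes, function(cl) {
      structure(list(w = as.numeric(p$model$weights[[cl]]),
                     loss = p$model$loss,
                     regularizer = p$model$regularizer,
                     reg_param = p$model$reg_param, config = cfg,
                     objective = numeric(0),
                     positive_class = cl, negative_class = ".rest", d = d),
                class = "linear_model")
    })
    names(models) <- classes
    structure(list(classes = classes, models = models, loss = p$model$loss,
                   d = d),
              class = "ovr_model")
  }
  structure(list(classifier = p$classifier, vocab = vocab, model = model,
                 ngram_orders = as.integer(p$ngram_orders),
                 min_df = as.integer(p$min_df),
                 stopwords = p$stopwords,
                 collapse_repeats = isTRUE(p$collapse_repeats),
                 config = cfg, classes = model$classes),
            class = "text_classifier")
}
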