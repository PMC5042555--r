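# Default class-discriminative vocabularies: disjoint word sets evoking the
# three cancer-literature classes the pipeline is aimed at.
.default_class_terms <- list(
  breast = c("mammary", "ductal", "tamoxifen", "brca1", "mammography",
             "lumpectomy", "estrogen", "her2", "lobular", "mastectomy"),
  lung = c("bronchial", "egfr", "smoking", "adenocarcinoma", "alveolar",
           "nsclc", "pleural", "spirometry", "emphysema", "bronchoscopy"),
  prostate = c("psa", "gleason", "androgen", "prostatectomy", "brachytherapy",
               "testosterone", "urological", "hyperplasia", "antigen",
               "castration")
)

.injected_stopwords <- c("the", "of", "and", "in", "to", "a", "with", "for",
                         "was", "were", "this", "that", "is", "on", "by")
.injected_punct <- c(".", ",", ";", ":", ")", "\"", "?")

#' Class specifications for the synthetic corpus generator
#'
#' Each class is defined by a label, a document count, a list of
#' class-specific (discriminative) terms and a signal level `s`: the
#' probability that a content token is drawn from the class's own terms
#' rather than from the shared background vocabulary. Discriminative term
#' lists must be disjoint across classes.
#'
#' @param labels class labels (default the three cancer types).
#' @param n_docs documents per class (recycled; default 200).
#' @param signal signal level `s` in \[0, 1\] (recycled; default 0.5).
#' @param terms named list of discriminative term vectors, one per label.
#' @return list of class `class_spec` entries.
#' @export
class_specs <- function(labels = c("breast", "lung", "prostate"),
                        n_docs = 200L, signal = 0.5,
                        terms = .default_class_terms[labels]) {
  if (length(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  n_docs <- rep_len(as.integer(n_docs), length(labels))
  signal <- rep_len(signal, length(labels))
  if (any(signal < 0 | signal > 1)) stop("signal must be in [0, 1]", call. = FALSE)
  if (is.null(names(terms))) names(terms) <- labels
  all_terms <- unlist(terms, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("discriminative vocabularies overlap across classes: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(seq_along(labels), function(i) {
    structure(list(label = labels[i], n_docs = n_docs[i],
                   terms = terms[[labels[i]]], signal = signal[i]),
              class = "class_spec")
  })
  names(specs) <- labels
  specs
}

#' Generator configuration
#'
#' Controls the corpus-wide properties of [generate_corpus()]: the size of
#' the Zipf-distributed shared vocabulary (so ubiquitous terms get TF-IDF
#' weight near zero, like real function-adjacent words), the rates at which
#' stop-words and punctuation are injected (so preprocessing has real work to
#' do), and the abstract-like document length distribution (negative
#' binomial; mean 150 tokens emulates abstracts, mean 3000 full text).
#'
#' @param shared_vocab_size number of background terms (default 500).
#' @param stopword_rate probability of inserting a stop-word at each token
#'   position (default 0.25).
#' @param punct_rate probability of attaching a punctuation mark to a token
#'   (default 0.1).
#' @param mean_length mean document length in content tokens (default 150).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param seed integer seed; the same configuration and seed give a
#'   byte-identical corpus.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(shared_vocab_size = 500L, stopword_rate = 0.25,
                             punct_rate = 0.1, mean_length = 150,
                             dispersion = 10, seed = 1L) {
  stopifnot(shared_vocab_size >= 1L, mean_length >= 1, dispersion > 0)
  if (any(c(stopword_rate, punct_rate) < 0) ||
      any(c(stopword_rate, punct_rate) > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(shared_vocab_size = as.integer(shared_vocab_size),
                 stopword_rate = stopword_rate, punct_rate = punct_rate,
                 mean_length = mean_length, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic pronounceable background vocabulary (no seed involvement)
.shared_vocab <- function(size, exclude) {
  syll <- as.vector(outer(c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                            "s", "t", "v", "z"),
                          c("a", "e", "i", "o", "u"), paste0))
  ns <- length(syll)
  words <- character(0)
  i <- 0L
  while (length(words) < size) {
    need <- size - length(words)
    idx <- i + seq_len(need * 2L)
    cand <- paste0(syll[(idx %% ns) + 1L],
                   syll[((idx %/% ns) %% ns) + 1L],
                   syll[((idx %/% (ns * ns)) %% ns) + 1L])
    i <- i + need * 2L
    words <- unique(c(words, setdiff(cand, exclude)))
  }
  words[seq_len(size)]
}

#' Generate a seeded labeled corpus with class-discriminative vocabulary
#'
#' Each document's content tokens are drawn from the mixture
#' `(1 - s) * shared + s * own-class` where the shared background vocabulary
#' follows a Zipf distribution and each class's discriminative terms are
#' drawn uniformly. Stop-words and punctuation are injected at the configured
#' rates and the first token is capitalized, so the raw text genuinely
#' exercises normalization, tokenization and stop-word removal.
#'
#' @param specs list from [class_specs()].
#' @param config a [generator_config()].
#' @return a labeled [corpus()], documents ordered by class then index.
#' @examples
#' co <- generate_corpus(class_specs(n_docs = 5), generator_config(seed = 1))
#' co
#' @export
generate_corpus <- function(specs = class_specs(),
                            config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (length(specs) < 2L) stop("need at least 2 classes", call. = FALSE)
  all_terms <- unlist(lapply(specs, `[[`, "terms"), use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("discriminative vocabularies overlap across classes", call. = FALSE)
  }
  shared <- .shared_vocab(config$shared_vocab_size,
                          exclude = c(all_terms, .injected_stopwords))
  zipf <- (1 / seq_along(shared))
  zipf <- zipf / sum(zipf)
  set.seed(config$seed)
  ids <- character(0); texts <- character(0); labs <- character(0)
  counter <- 0L
  for (spec in specs) {
    for (i in seq_len(spec$n_docs)) {
      counter <- counter + 1L
      len <- max(5L, stats::rnbinom(1L, size = config$dispersion,
                                    mu = config$mean_length))
      own <- stats::runif(len) < spec$signal
      content <- character(len)
      content[own] <- sample(spec$terms, sum(own), replace = TRUE)
      content[!own] <- sample(shared, sum(!own), replace = TRUE, prob = zipf)
      # inject stop-words before a fraction of positions
      with_stop <- stats::runif(len) < config$stopword_rate
      tokens <- unlist(lapply(seq_len(len), function(j) {
        if (with_stop[j]) c(sample(.injected_stopwords, 1L), content[j])
        else content[j]
      }), use.names = FALSE)
      # attach punctuation to a fraction of tokens
      punct <- stats::runif(length(tokens)) < config$punct_rate
      tokens[punct] <- paste0(tokens[punct],
                              sample(.injected_punct, sum(punct),
                                     replace = TRUE))
      substr(tokens[1L], 1L, 1L) <- toupper(substr(tokens[1L], 1L, 1L))
      ids <- c(ids, sprintf("d%05d", counter))
      texts <- c(texts, paste(tokens, collapse = " "))
      labs <- c(labs, spec$label)
    }
  }
  corpus(ids, texts, labs)
}

#' Generate Gaussian point clusters for classifier unit tests
#'
#' Draws `n_per_class` points from an isotropic Gaussian around each mean.
#' With inter-mean distance much larger than `sigma` the classes are linearly
#' separable by construction.
#'
#' @param n_per_class points per class.
#' @param means numeric matrix, one row per class mean (default two 2-D
#'   clusters at (-2, 0) and (2, 0)).
#' @param sigma isotropic spread (>= 0; 0 puts every point at its mean).
#' @param seed integer seed.
#' @return list with `X` (numeric matrix, columns `x1`, `x2`, ...) and
#'   `labels` (character, `"c1"`, `"c2"`, ... by mean row).
#' @export
generate_blobs <- function(n_per_class = 50L,
                           means = rbind(c(-2, 0), c(2, 0)),
                           sigma = 0.3, seed = 1L) {
  means <- as.matrix(means)
  if (anyDuplicated(means)) stop("class means must be distinct", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  set.seed(seed)
  k <- nrow(means)
  d <- ncol(means)
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    sweep(matrix(stats::rnorm(n_per_class * d, sd = sigma),
                 nrow = n_per_class), 2L, means[c, ], `+`)
  }))
  colnames(X) <- paste0("x", seq_len(d))
  list(X = X, labels = rep(paste0("c", seq_len(k)), each = n_per_class))
}
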