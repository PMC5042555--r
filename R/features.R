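#' Extract n-grams from a token sequence
#'
#' For order 1 each token is a term; for order 2 each pair of adjacent tokens
#' is joined with `"-"` (e.g. `"breast-cancer"`). Output lists all unigrams in
#' token order, then all bigrams in token order.
#'
#' @param tokens character vector of (stemmed) tokens.
#' @param orders integer vector of n-gram orders, subset of `1:2` by default
#'   (higher orders are accepted).
#' @return character vector of terms.
#' @examples
#' extract_ngrams(c("breast", "cancer", "incid"), orders = c(1, 2))
#' @export
extract_ngrams <- function(tokens, orders = c(1L, 2L)) {
  orders <- sort(unique(as.integer(orders)))
  if (length(orders) == 0L) stop("`orders` must be non-empty", call. = FALSE)
  if (any(orders < 1L)) stop("n-gram orders must be >= 1", call. = FALSE)
  n <- length(tokens)
  out <- character(0)
  for (k in orders) {
    if (n >= k) {
      if (k == 1L) {
        grams <- tokens
      } else {
        idx <- seq_len(n - k + 1L)
        pieces <- lapply(seq_len(k) - 1L, function(o) tokens[idx + o])
        grams <- do.call(paste, c(pieces, sep = "-"))
      }
      out <- c(out, grams)
    }
  }
  out
}

#' Build a unigram/bigram vocabulary with document frequencies
#'
#' Counts, for every term, the number of documents whose n-gram set contains
#' it (`DF_t`), drops terms seen in fewer than `min_df` documents (the
#' rare-word filter), and assigns each surviving term a position by
#' lexicographic order, so repeated builds on the same input give identical
#' indices.
#'
#' @param token_seqs list of token sequences (one per document), e.g. from
#'   [preprocess_corpus()].
#' @param orders n-gram orders, default unigrams + bigrams.
#' @param min_df minimum document frequency for a term to be indexed
#'   (default 2).
#' @return an object of class `vocabulary`: list with `terms` (character, in
#'   index order), `df` (integer document frequencies, parallel to `terms`),
#'   `n_docs`, `orders`, `min_df`.
#' @export
build_vocabulary <- function(token_seqs, orders = c(1L, 2L), min_df = 2L) {
  if (!is.list(token_seqs) || length(token_seqs) == 0L) {
    stop("`token_seqs` must be a non-empty list", call. = FALSE)
  }
  if (min_df < 1L) stop("`min_df` must be >= 1", call. = FALSE)
  per_doc <- lapply(token_seqs, function(tok) {
    unique(extract_ngrams(tok, orders))
  })
  tab <- table(unlist(per_doc, use.names = FALSE))
  df <- as.integer(tab)
  terms <- names(tab)
  keep <- df >= min_df
  terms <- terms[keep]
  df <- df[keep]
  ord <- order(terms, method = "radix")
  structure(list(terms = terms[ord], df = df[ord],
                 n_docs = length(token_seqs),
                 orders = sort(unique(as.integer(orders))),
                 min_df = as.integer(min_df)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms over %d documents (orders %s, min_df %d)\n",
              length(x$terms), x$n_docs, paste(x$orders, collapse = ","),
              x$min_df))
  invisible(x)
}

#' TF-IDF weight of a term in a document
#'
#' Computes `W = TF * log10(N / DF)`: the raw in-document term frequency
#' scaled by the inverse document frequency. A term present in every document
#' (`DF = N`) gets weight 0 — it carries no class information — as does a term
#' absent from the document (`TF = 0`).
#'
#' @param tf raw term frequency in the document (count, >= 0). Vectorized.
#' @param df document frequency of the term in the corpus.
#' @param n_docs number of documents `N` in the corpus (>= 1).
#' @return numeric TF-IDF weight(s), non-negative.
#' @examples
#' tfidf_weight(56, 1000, 1000)  # ubiquitous term: weight 0
#' tfidf_weight(3, 10, 1000)     # 3 * log10(100) = 6
#' @export
tfidf_weight <- function(tf, df, n_docs) {
  if (any(n_docs < 1)) stop("`n_docs` must be >= 1", call. = FALSE)
  if (any(df > n_docs)) stop("`df` cannot exceed `n_docs`", call. = FALSE)
  if (any(tf < 0) || any(df < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(df == 0 & tf > 0)) {
    stop("df = 0 for a term with tf > 0: term claimed present but in no document",
         call. = FALSE)
  }
  ifelse(tf == 0, 0, tf * log10(n_docs / df))
}

# raw term frequencies of vocabulary terms in one document's n-gram list
.term_counts <- function(tokens, vocab) {
  grams <- extract_ngrams(tokens, vocab$orders)
  if (length(grams) == 0L) return(integer(length(vocab$terms)))
  pos <- match(grams, vocab$terms)
  tabulate(pos[!is.na(pos)], nbins = length(vocab$terms))
}

#' TF-IDF feature vector of one document
#'
#' Vectorizes a token sequence against a fixed vocabulary: every document
#' gets an equal-length vector (dimension = vocabulary size) whose entries
#' are [tfidf_weight()] values; terms outside the vocabulary are ignored.
#'
#' @param tokens character vector of (stemmed) tokens.
#' @param vocab a [build_vocabulary()] result.
#' @return a sparse numeric vector (`Matrix::sparseVector`) of length
#'   `length(vocab$terms)`.
#' @export
vectorize_document <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  tf <- .term_counts(tokens, vocab)
  w <- tfidf_weight(tf, vocab$df, vocab$n_docs)
  nz <- which(w > 0)
  Matrix::sparseVector(x = w[nz], i = nz, length = length(vocab$terms))
}

#' TF-IDF document-term matrix of a corpus
#'
#' @param token_seqs named list of token sequences (names = doc ids).
#' @param vocab a [build_vocabulary()] result — typically built on the
#'   training portion only, so test documents never influence the IDF.
#' @return sparse `dgCMatrix`, rows = documents, columns = vocabulary terms.
#' @export
vectorize_corpus <- function(token_seqs, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  d <- length(vocab$terms)
  triplets <- lapply(seq_along(token_seqs), function(i) {
    tf <- .term_counts(token_seqs[[i]], vocab)
    w <- tfidf_weight(tf, vocab$df, vocab$n_docs)
    nz <- which(w > 0)
    list(i = rep.int(i, length(nz)), j = nz, x = w[nz])
  })
  X <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(length(token_seqs), d),
    dimnames = list(names(token_seqs), vocab$terms)
  )
  Matrix::drop0(X)
}

#' Write / read a vocabulary sidecar file
#'
#' Plain tab-separated file: one `term<TAB>index<TAB>df` line per term, with
#' header comments recording the corpus size and settings.
#'
#' @param vocab a `vocabulary`.
#' @param path output path.
#' @return `path` invisibly (writer); a `vocabulary` (reader).
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  header <- c(sprintf("# n_docs\t%d", vocab$n_docs),
              sprintf("# orders\t%s", paste(vocab$orders, collapse = ",")),
              sprintf("# min_df\t%d", vocab$min_df))
  body <- sprintf("%s\t%d\t%d", vocab$terms, seq_along(vocab$terms), vocab$df)
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key, "\t"), meta)]
    if (!length(ln)) stop("vocabulary file lacks '", key, "' header", call. = FALSE)
    sub(paste0("^# ", key, "\t"), "", ln[1L])
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed vocabulary line", call. = FALSE)
  }
  terms <- vapply(parts, `[[`, character(1L), 1L)
  idx <- as.integer(vapply(parts, `[[`, character(1L), 2L))
  df <- as.integer(vapply(parts, `[[`, character(1L), 3L))
  ord <- order(idx)
  structure(list(terms = terms[ord], df = df[ord],
                 n_docs = as.integer(get_meta("n_docs")),
                 orders = as.integer(strsplit(get_meta("orders"), ",")[[1L]]),
                 min_df = as.integer(get_meta("min_df"))),
            class = "vocabulary")
}

#' Write / read feature vectors in SVMlight sparse format
#'
#' One line per document: `label index:value ...` with 1-based indices in
#' increasing order.
#'
#' @param X sparse document-term matrix (`dgCMatrix`).
#' @param labels numeric labels, one per row of `X`.
#' @param path file path.
#' @param dimension vector dimension; by default inferred from the largest
#'   index in the file.
#' @return `path` invisibly (writer); list with `X` and `labels` (reader).
#' @export
write_svmlight <- function(X, labels, path) {
  X <- methods::as(X, "CsparseMatrix")
  stopifnot(nrow(X) == length(labels))
  Xt <- Matrix::t(X)  # column-per-document for fast row extraction
  p <- Xt@p
  lines <- vapply(seq_len(nrow(X)), function(i) {
    idx <- seq.int(p[i] + 1L, length.out = p[i + 1L] - p[i])
    feats <- sprintf("%d:%.10g", Xt@i[idx] + 1L, Xt@x[idx])
    paste(c(format(labels[i], scientific = FALSE, trim = TRUE), feats),
          collapse = " ")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_svmlight
#' @export
read_svmlight <- function(path, dimension = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labels <- numeric(length(lines))
  ii <- list(); jj <- list(); xx <- list()
  for (r in seq_along(lines)) {
    parts <- strsplit(trimws(lines[r]), "\\s+")[[1L]]
    labels[r] <- as.numeric(parts[1L])
    if (length(parts) > 1L) {
      kv <- strsplit(parts[-1L], ":", fixed = TRUE)
      jj[[r]] <- as.integer(vapply(kv, `[[`, character(1L), 1L))
      xx[[r]] <- as.numeric(vapply(kv, `[[`, character(1L), 2L))
      ii[[r]] <- rep.int(r, length(kv))
    }
  }
  j <- unlist(jj)
  if (is.null(dimension)) dimension <- if (length(j)) max(j) else 0L
  X <- Matrix::sparseMatrix(i = unlist(ii), j = j, x = unlist(xx),
                            dims = c(length(lines), dimension))
  list(X = X, labels = labels)
}
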