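#' Normalize raw text
#'
#' Lower-cases the input and replaces every character outside `a-z`, `0-9`
#' and whitespace with a single space. Punctuation — including hyphens and
#' quotation marks — therefore becomes a token boundary; digits are kept so
#' biomedical symbols such as `p53` survive intact.
#'
#' @param text character vector of raw text.
#' @return character vector of normalized text, same length as `text`.
#' @examples
#' normalize_text("Breast Cancer!")
#' normalize_text("p53-mediated")
#' @export
normalize_text <- function(text) {
  if (!is.character(text)) stop("`text` must be character", call. = FALSE)
  gsub("[^a-z0-9 \t\r\n]", " ", tolower(text))
}

#' Split normalized text into tokens
#'
#' Splits on runs of whitespace and drops empty strings. Input is expected to
#' be already normalized (see [normalize_text()]).
#'
#' @param text a single normalized string.
#' @return character vector of tokens (possibly empty).
#' @examples
#' tokenize("breast cancer")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[ \t\r\n]+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Load a stop-word list
#'
#' Reads one lowercase term per line; blank lines and `#` comments are
#' ignored. With `path = NULL` the bundled English list is used ("user-defined
#' stop-words" may be supplied instead).
#'
#' @param path path to a stop-word file, or `NULL` for the bundled default.
#' @return character vector of unique lowercase stop-words.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "litclass")
  }
  if (!file.exists(path)) stop("stop-word file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' Remove stop-words from a token sequence
#'
#' @param tokens character vector of lowercase tokens.
#' @param stopwords character vector of stop-words (lowercase).
#' @return `tokens` with stop-words removed, order preserved.
#' @examples
#' remove_stopwords(c("the", "incidence", "of", "breast"), c("the", "of"))
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

# collapse runs of >= 3 identical characters to a single character
.collapse_repeats <- function(tokens) {
  gsub("(.)\\1{2,}", "\\1", tokens)
}

#' Preprocess one document into a stemmed token sequence
#'
#' Applies the full preprocessing chain in order: normalization ->
#' tokenization -> stop-word removal -> optional repeated-character collapse
#' -> Porter stemming. The result is the token sequence from which n-gram
#' features are extracted.
#'
#' @param text a single raw text string (or a one-row [corpus()]).
#' @param stopwords character vector of stop-words; defaults to the bundled
#'   English list.
#' @param collapse_repeats collapse runs of three or more identical characters
#'   to one before stemming? Default `FALSE` (scientific prose rarely needs
#'   it).
#' @return character vector of stems.
#' @examples
#' preprocess_document("The incidence of breast cancer.")
#' @export
preprocess_document <- function(text, stopwords = load_stopwords(),
                                collapse_repeats = FALSE) {
  if (inherits(text, "corpus")) {
    stopifnot(nrow(text) == 1L)
    text <- text$text
  }
  tokens <- tokenize(normalize_text(text))
  tokens <- remove_stopwords(tokens, stopwords)
  if (collapse_repeats) tokens <- .collapse_repeats(tokens)
  porter_stem(tokens)
}

#' Preprocess every document of a corpus
#'
#' @param x a [corpus()].
#' @inheritParams preprocess_document
#' @return named list of stem vectors, one per document, names = `doc_id`.
#' @export
preprocess_corpus <- function(x, stopwords = load_stopwords(),
                              collapse_repeats = FALSE) {
  stopifnot(inherits(x, "corpus"))
  token_lists <- lapply(x$text, function(txt) {
    tokens <- tokenize(normalize_text(txt))
    tokens <- remove_stopwords(tokens, stopwords)
    if (collapse_repeats) tokens <- .collapse_repeats(tokens)
    tokens
  })
  # stem each distinct surface token once, then map back
  all_tokens <- unique(unlist(token_lists, use.names = FALSE))
  stems <- porter_stem(all_tokens)
  out <- lapply(token_lists, function(tok) {
    unname(stems[match(tok, all_tokens)])
  })
  names(out) <- x$doc_id
  out
}
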