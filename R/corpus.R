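#' Construct a labeled document corpus
#'
#' A corpus is an ordered collection of documents, each with a unique
#' `doc_id`, free text and an optional class label. It is represented as a
#' `data.frame` with columns `doc_id`, `text`, `label` and class `"corpus"`.
#'
#' @param doc_id character vector of unique, non-empty document identifiers.
#' @param text character vector of document texts. Empty texts are allowed
#'   (with a warning).
#' @param label optional character vector of class labels (`NA` = unlabeled).
#' @return an object of class `corpus`.
#' @examples
#' corpus(c("1", "2"), c("breast cancer study", "lung cancer study"),
#'        c("breast", "lung"))
#' @export
corpus <- function(doc_id, text, label = NA_character_) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  label <- as.character(label)
  if (length(label) == 1L) label <- rep(label, length(doc_id))
  if (length(text) != length(doc_id) || length(label) != length(doc_id)) {
    stop("doc_id, text and label must have equal lengths", call. = FALSE)
  }
  if (any(is.na(doc_id)) || any(!nzchar(doc_id))) {
    stop("every doc_id must be non-empty", call. = FALSE)
  }
  dup <- doc_id[duplicated(doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  text[is.na(text)] <- ""
  if (any(!nzchar(text))) {
    warning(sum(!nzchar(text)), " document(s) have empty text", call. = FALSE)
  }
  out <- data.frame(doc_id = doc_id, text = text, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("corpus", "data.frame")
  out
}

#' @export
print.corpus <- function(x, ...) {
  cls <- corpus_classes(x)
  cat(sprintf("<corpus> %d documents, %d class(es)%s\n", nrow(x), length(cls),
              if (length(cls)) paste0(": ", paste(cls, collapse = ", ")) else ""))
  invisible(x)
}

#' Class labels observed in a corpus
#'
#' @param x a [corpus()].
#' @return sorted character vector of distinct non-missing labels.
#' @export
corpus_classes <- function(x) {
  stopifnot(inherits(x, "corpus"))
  sort(unique(x$label[!is.na(x$label)]), method = "radix")
}

#' Read a MEDLINE flat file
#'
#' Parses NLM's tagged flat-file format (`PMID- `, `TI  - `, `AB  - `;
#' continuation lines indented with six spaces; records separated by blank
#' lines). Each record becomes one document whose text is the title and
#' abstract joined by a single space and whose `doc_id` is the PMID. Labels
#' are not part of MEDLINE records; they may be supplied through a sidecar
#' file of `doc_id<TAB>label` lines (`#` comments allowed).
#'
#' @param path path to the MEDLINE file.
#' @param label_file optional path to a two-column tab-separated label file.
#' @return a [corpus()].
#' @export
read_medline <- function(path, label_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split into records on blank lines
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1L]))
  if (length(lines) == 0L || all(blank)) {
    return(corpus(character(0), character(0), character(0)))
  }
  records <- split(lines[!blank], rec_id[!blank])
  parse_record <- function(rec_lines, idx) {
    fields <- list()
    tag <- NULL
    for (ln in rec_lines) {
      if (grepl("^ {6}", ln)) {
        if (is.null(tag)) next
        fields[[tag]] <- paste(fields[[tag]], trimws(ln))
      } else if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
        tag <- trimws(sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln))
        content <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
        fields[[tag]] <- if (is.null(fields[[tag]])) content
                         else paste(fields[[tag]], content)
      }
    }
    if (is.null(fields$PMID)) {
      stop("MEDLINE record ", idx, " has no PMID", call. = FALSE)
    }
    text <- paste(c(fields$TI, fields$AB), collapse = " ")
    c(pmid = trimws(fields$PMID), text = text)
  }
  parsed <- mapply(parse_record, records, seq_along(records), SIMPLIFY = FALSE)
  pmid <- vapply(parsed, `[[`, character(1L), "pmid")
  dup <- pmid[duplicated(pmid)]
  if (length(dup)) {
    stop("duplicate PMID: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  text <- vapply(parsed, `[[`, character(1L), "text")
  label <- rep(NA_character_, length(pmid))
  if (!is.null(label_file)) {
    if (!file.exists(label_file)) {
      stop("label file not found: ", label_file, call. = FALSE)
    }
    lab_lines <- readLines(label_file, encoding = "UTF-8", warn = FALSE)
    lab_lines <- trimws(sub("#.*$", "", lab_lines))
    lab_lines <- lab_lines[nzchar(lab_lines)]
    parts <- strsplit(lab_lines, "\t", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop("label file line ", which(bad)[1L], " is not 'doc_id<TAB>label'",
           call. = FALSE)
    }
    ids <- vapply(parts, `[[`, character(1L), 1L)
    labs <- vapply(parts, `[[`, character(1L), 2L)
    label <- labs[match(pmid, ids)]
  }
  corpus(pmid, text, label)
}

#' Read a labeled corpus (JSONL or CSV)
#'
#' JSONL: one object per line with fields `id`, `text`, `label` (UTF-8).
#' CSV: header `id,text,label` with RFC-4180 quoting.
#'
#' @param path input file path.
#' @param dialect `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return a [corpus()].
#' @export
read_labeled <- function(path, dialect = c("auto", "jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop("line ", i, ": invalid JSON (", conditionMessage(e),
                             ")", call. = FALSE)
                      })
      for (f in c("id", "text", "label")) {
        if (is.null(rec[[f]])) {
          stop("line ", i, ": missing field '", f, "'", call. = FALSE)
        }
      }
      rec
    })
    get <- function(f) vapply(recs, function(r) {
      v <- r[[f]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) NA_character_
      else as.character(v)
    }, character(1L))
    corpus(get("id"), get("text"), get("label"))
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          encoding = "UTF-8", check.names = FALSE)
    for (f in c("id", "text", "label")) {
      if (!f %in% names(df)) {
        stop("CSV is missing column '", f, "'", call. = FALSE)
      }
    }
    lab <- df$label
    lab[!nzchar(lab)] <- NA_character_
    corpus(df$id, df$text, lab)
  }
}

#' Write a labeled corpus (JSONL or CSV)
#'
#' Inverse of [read_labeled()]: a write followed by a read reproduces
#' `doc_id`, `text` and `label` exactly, in the same order.
#'
#' @param x a [corpus()].
#' @param path output file path.
#' @param dialect `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_labeled <- function(x, path, dialect = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(x, "corpus"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      jsonlite::toJSON(list(id = x$doc_id[i], text = x$text[i],
                            label = x$label[i]),
                       auto_unbox = TRUE, na = "null")
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(id = x$doc_id, text = x$text,
                     label = ifelse(is.na(x$label), "", x$label),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Split a corpus into training and testing parts
#'
#' Performs a seeded uniform shuffle and cuts the first
#' `round(n * train_fraction)` documents (round-half-up) into the training
#' part; the remainder is the test part. The parts are disjoint and their
#' union is the input.
#'
#' @param x a non-empty [corpus()].
#' @param train_fraction proportion of documents for training, in (0, 1).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return list with elements `train` and `test`, both [corpus()] objects.
#' @examples
#' co <- corpus(as.character(1:10), rep("text", 10), rep(c("a", "b"), 5))
#' sp <- train_test_split(co, 0.8, seed = 7)
#' nrow(sp$train); nrow(sp$test)
#' @export
train_test_split <- function(x, train_fraction, seed) {
  stopifnot(inherits(x, "corpus"))
  n <- nrow(x)
  if (n == 0L) stop("corpus is empty", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- as.integer(floor(n * train_fraction + 0.5))
  set.seed(seed)
  perm <- sample.int(n)
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[seq.int(n_train + 1L, length.out = n - n_train)])
  list(train = x[idx_train, , drop = FALSE],
       test = x[idx_test, , drop = FALSE])
}

#' @export
`[.corpus` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("doc_id", "text", "label") %in% names(out))) {
    rownames(out) <- NULL
    class(out) <- c("corpus", "data.frame")
  }
  out
}
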