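# Porter stemmer (1980), with the author's two later published departures:
#   step 2: (m>0) bli -> ble   (replaces abli -> able)
#   step 2:       logi -> log  (measure taken on the word minus "ogi", so the
#                               "l" counts; biology -> biologi -> biolog)

.pm_vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel profile of a word; "y" is a vowel iff preceded by a consonant
.pm_cons <- function(chars) {
  n <- length(chars)
  out <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    out[i] <- if (ch %in% .pm_vowels) {
      FALSE
    } else if (ch == "y") {
      if (i == 1L) TRUE else !out[i - 1L]
    } else {
      TRUE
    }
  }
  out
}

# the measure m: number of vowel->consonant transitions, i.e. m in [C](VC)^m[V]
.pm_m <- function(word) {
  if (nchar(word) < 2L) return(0L)
  cv <- .pm_cons(strsplit(word, "", fixed = TRUE)[[1L]])
  n <- length(cv)
  sum(!cv[-n] & cv[-1L])
}

.pm_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.pm_cons(strsplit(word, "", fixed = TRUE)[[1L]]))
}

.pm_ends <- function(word, suffix) {
  nw <- nchar(word)
  ns <- nchar(suffix)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.pm_chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# *d: word ends in a double consonant
.pm_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  chars[n] == chars[n - 1L] && .pm_cons(chars)[n]
}

# *o: word ends consonant-vowel-consonant where the final consonant is not w/x/y
.pm_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  cv <- .pm_cons(chars)
  cv[n] && !cv[n - 1L] && cv[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.pm_step1a <- function(w) {
  if (.pm_ends(w, "sses")) return(.pm_chop(w, 2L))
  if (.pm_ends(w, "ies")) return(.pm_chop(w, 2L))
  if (.pm_ends(w, "ss")) return(w)
  if (.pm_ends(w, "s")) return(.pm_chop(w, 1L))
  w
}

.pm_step1b <- function(w) {
  if (.pm_ends(w, "eed")) {
    if (.pm_m(.pm_chop(w, 3L)) > 0L) w <- .pm_chop(w, 1L)
    return(w)
  }
  stripped <- FALSE
  if (.pm_ends(w, "ed") && .pm_has_vowel(.pm_chop(w, 2L))) {
    w <- .pm_chop(w, 2L)
    stripped <- TRUE
  } else if (.pm_ends(w, "ing") && .pm_has_vowel(.pm_chop(w, 3L))) {
    w <- .pm_chop(w, 3L)
    stripped <- TRUE
  }
  if (stripped) {
    if (.pm_ends(w, "at") || .pm_ends(w, "bl") || .pm_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pm_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- .pm_chop(w, 1L)
    } else if (.pm_m(w) == 1L && .pm_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.pm_step1c <- function(w) {
  if (.pm_ends(w, "y") && .pm_has_vowel(.pm_chop(w, 1L))) {
    w <- paste0(.pm_chop(w, 1L), "i")
  }
  w
}

.pm_step2_rules <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
  c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"), c("iviti", "ive"),
  c("enci", "ence"), c("anci", "ance"), c("izer", "ize"), c("alli", "al"),
  c("ator", "ate"), c("logi", "log"), c("bli", "ble"), c("eli", "e")
)

.pm_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

# longest matching suffix wins; its condition decides, no fallback
.pm_apply_rules <- function(w, rules, special_logi = FALSE) {
  match_len <- 0L
  repl <- NULL
  suf <- NULL
  for (rule in rules) {
    s <- rule[[1L]]
    if (nchar(s) > match_len && .pm_ends(w, s)) {
      match_len <- nchar(s)
      suf <- s
      repl <- rule[[2L]]
    }
  }
  if (is.null(suf)) return(w)
  stem <- .pm_chop(w, nchar(suf))
  measured <- if (special_logi && suf == "logi") .pm_chop(w, 3L) else stem
  if (.pm_m(measured) > 0L) paste0(stem, repl) else w
}

.pm_step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
  "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

.pm_step4 <- function(w) {
  match_len <- 0L
  suf <- NULL
  for (s in .pm_step4_suffixes) {
    if (nchar(s) > match_len && .pm_ends(w, s)) {
      match_len <- nchar(s)
      suf <- s
    }
  }
  if (is.null(suf)) return(w)
  stem <- .pm_chop(w, nchar(suf))
  if (.pm_m(stem) <= 1L) return(w)
  if (suf == "ion" &&
      !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
    return(w)
  }
  stem
}

.pm_step5a <- function(w) {
  if (substr(w, nchar(w), nchar(w)) == "e") {
    stem <- .pm_chop(w, 1L)
    m <- .pm_m(stem)
    if (m > 1L || (m == 1L && !.pm_cvc(stem))) w <- stem
  }
  w
}

.pm_step5b <- function(w) {
  if (.pm_m(w) > 1L && .pm_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- .pm_chop(w, 1L)
  }
  w
}

.pm_stem_one <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  w <- .pm_step1a(w)
  w <- .pm_step1b(w)
  w <- .pm_step1c(w)
  w <- .pm_apply_rules(w, .pm_step2_rules, special_logi = TRUE)
  w <- .pm_apply_rules(w, .pm_step3_rules)
  w <- .pm_step4(w)
  w <- .pm_step5a(w)
  .pm_step5b(w)
}

#' Porter stem of a word
#'
#' Reduces English words to their Porter (1980) stems, e.g. `"biology"` and
#' `"biological"` both map to `"biolog"`, so that inflectional variants share
#' one vocabulary entry. Includes the algorithm author's two later published
#' refinements to step 2 (`bli -> ble`, `logi -> log`). Words of length two or
#' less, and tokens containing characters outside `a-z` (e.g. gene symbols
#' like `"p53"`), are returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`. Stems are never
#'   longer than their input, and stemming is idempotent.
#' @examples
#' porter_stem(c("biology", "biopsy", "survival", "almost"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) stop("`words` must be a character vector", call. = FALSE)
  vapply(words, .pm_stem_one, character(1L), USE.NAMES = FALSE)
}
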