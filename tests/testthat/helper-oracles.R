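# Independent oracles and small fixtures shared across tests.

# AUC as the Mann-Whitney probability by exhaustive pair counting (ties = 1/2)
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# Multinomial naive Bayes by direct enumeration: plain loops over a dense
# count matrix, no shared code with the implementation.
nb_enum_oracle <- function(X, y, lambda, probe) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  d <- ncol(X)
  joint <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    rows <- which(y == cl)
    prior <- length(rows) / length(y)
    sums <- numeric(d)
    for (r in rows) {
      for (j in seq_len(d)) sums[j] <- sums[j] + X[r, j]
    }
    theta <- (sums + lambda) / (sum(sums) + lambda * d)
    ll <- log(prior)
    for (j in seq_len(d)) ll <- ll + probe[j] * log(theta[j])
    joint[cl] <- ll
  }
  list(label = names(which.max(joint)), log_joint = joint,
       posterior = exp(joint - max(joint)) / sum(exp(joint - max(joint))))
}

# tiny labeled corpus with known class-specific vocabulary
tiny_corpus <- function() {
  corpus(
    doc_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    text = c("mammary ductal tumor growth", "mammary tumor screening",
             "bronchial airway tumor growth", "bronchial tumor nodule",
             "gleason antigen tumor growth", "gleason tumor grading"),
    label = c("breast", "breast", "lung", "lung", "prostate", "prostate")
  )
}

write_medline_fixture <- function(path, records) {
  writeLines(paste(records, collapse = "\n\n"), path)
  path
}
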