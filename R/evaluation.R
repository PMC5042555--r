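#' Confusion counts against a designated positive class
#'
#' Tallies one-vs-rest outcomes: a prediction counts as positive iff it
#' equals `positive`, and likewise for the truth.
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels, same length.
#' @param positive the class treated as positive.
#' @return object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`,
#'   `P = TP + FN` and `N = TN + FP`.
#' @examples
#' confusion_counts(c("+", "+", "-"), c("+", "-", "-"), positive = "+")
#' @export
confusion_counts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) stop("no instances to evaluate", call. = FALSE)
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(list(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
                 FP = sum(!tpos & ppos), FN = sum(tpos & !ppos),
                 P = sum(tpos), N = sum(!tpos), positive = positive),
            class = "confusion_counts")
}

#' Accuracy, precision and recall from confusion counts
#'
#' `ACC = (TP + TN) / (P + N)`, `PPV = TP / (TP + FP)`,
#' `TPR = TP / (TP + FN)`. A ratio with zero denominator is reported as `NA`
#' with a warning, never silently as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return object of class `metrics_report` with `accuracy`, `precision`,
#'   `recall` and the underlying `counts`.
#' @examples
#' classification_metrics(confusion_counts(
#'   rep(c("+", "-"), c(11, 9)),
#'   rep(c("+", "-", "+", "-"), c(9, 2, 1, 8)), positive = "+"))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$P + counts$N
  if (total < 1L) stop("empty confusion counts", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      NA_real_
    } else {
      num / den
    }
  }
  structure(list(
    accuracy = (counts$TP + counts$TN) / total,
    precision = ratio(counts$TP, counts$TP + counts$FP, "precision"),
    recall = ratio(counts$TP, counts$TP + counts$FN, "recall"),
    counts = counts
  ), class = "metrics_report")
}

#' Multiclass metrics by one-vs-rest averaging
#'
#' Computes overall accuracy plus precision and recall averaged over
#' one-vs-rest reductions: `"macro"` averages the per-class ratios (classes
#' weigh equally), `"micro"` pools the per-class confusion counts first.
#' Per-class values with zero denominators are dropped from the macro mean
#' (with a warning from the per-class computation).
#'
#' @param truth,predicted character label vectors of equal length.
#' @param average `"macro"` (default) or `"micro"`.
#' @return list with `accuracy`, `precision`, `recall`, `per_class`
#'   (data.frame) and `average`.
#' @export
multiclass_metrics <- function(truth, predicted, average = c("macro", "micro")) {
  average <- match.arg(average)
  classes <- sort(unique(as.character(truth)), method = "radix")
  counts <- lapply(classes, function(cl) confusion_counts(truth, predicted, cl))
  per <- lapply(counts, function(cc) suppressWarnings(classification_metrics(cc)))
  per_class <- data.frame(
    class = classes,
    precision = vapply(per, `[[`, numeric(1L), "precision"),
    recall = vapply(per, `[[`, numeric(1L), "recall")
  )
  if (average == "macro") {
    precision <- mean(per_class$precision, na.rm = TRUE)
    recall <- mean(per_class$recall, na.rm = TRUE)
  } else {
    tp <- sum(vapply(counts, `[[`, numeric(1L), "TP"))
    fp <- sum(vapply(counts, `[[`, numeric(1L), "FP"))
    fn <- sum(vapply(counts, `[[`, numeric(1L), "FN"))
    precision <- tp / (tp + fp)
    recall <- tp / (tp + fn)
  }
  list(accuracy = mean(truth == predicted), precision = precision,
       recall = recall, per_class = per_class, average = average)
}

#' Partition indices into k folds
#'
#' Seeded uniform shuffle of `1:n` dealt into `k` folds whose sizes differ by
#' at most one. Each fold in turn serves as the test set of one
#' cross-validation round.
#'
#' @param n number of instances.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @return list of `k` disjoint integer index vectors covering `1:n`.
#' @export
kfold_indices <- function(n, k, seed) {
  if (k < 2L || k > n) stop("`k` must satisfy 2 <= k <= n", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Stratified k-fold indices
#'
#' Shuffles each class separately and deals its members round-robin across
#' folds, so every fold mirrors the corpus class proportions.
#'
#' @param labels character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` disjoint index vectors covering `seq_along(labels)`.
#' @export
stratified_kfold_indices <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L || k > n) stop("`k` must satisfy 2 <= k <= n", call. = FALSE)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop("class '", small[1L], "' has fewer than k = ", k, " members",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cl in sort(names(counts), method = "radix")) {
    idx <- sample(which(labels == cl))
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the observed scores (equal scores are
#' grouped into a single step) and returns the (FPR, TPR) curve from (0, 0)
#' to (1, 1) with its trapezoidal area. With tied scores the AUC equals the
#' Mann-Whitney probability with ties counted 1/2.
#'
#' @param scores numeric decision scores, larger = more positive. Use the
#'   decision score `z` for SVM, the sigmoid probability for logistic
#'   regression, and the posterior (or top-two log-posterior margin) for
#'   naive Bayes.
#' @param truth logical vector (or 0/1) — `TRUE` for the positive class;
#'   both classes must be present.
#' @return object of class `roc_curve`: data.frame `points` with columns
#'   `fpr`, `tpr`, and scalar `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` must have equal length", call. = FALSE)
  }
  if (all(truth) || !any(truth)) {
    stop("both classes must be present in `truth`", call. = FALSE)
  }
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(pROC::auc(r))),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' One-vs-rest ROC analysis for a multiclass task
#'
#' Computes one ROC curve per class (that class positive, scored by its
#' column of `scores`) and the macro-averaged AUC. With two classes the
#' macro AUC equals the binary AUC.
#'
#' @param scores matrix of per-class scores (columns named by class).
#' @param truth character vector of true labels.
#' @return list with `curves` (named list of [roc_auc()] results) and
#'   `macro_auc`.
#' @export
roc_ovr <- function(scores, truth) {
  classes <- colnames(scores)
  if (is.null(classes)) stop("`scores` must have class column names", call. = FALSE)
  curves <- lapply(classes, function(cl) {
    roc_auc(scores[, cl], truth == cl)
  })
  names(curves) <- classes
  list(curves = curves,
       macro_auc = mean(vapply(curves, `[[`, numeric(1L), "auc")))
}
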