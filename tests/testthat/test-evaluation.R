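test_that("confusion counts tally one-vs-rest outcomes", {
  cc <- confusion_counts(c("+", "+", "-"), c("+", "-", "-"), positive = "+")
  expect_equal(cc[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 0L))
  perfect <- confusion_counts(c("a", "b"), c("a", "b"), positive = "a")
  expect_equal(perfect$FP + perfect$FN, 0L)
  allpos <- confusion_counts(rep("-", 4), rep("+", 4), positive = "+")
  expect_equal(allpos$FP, 4L)
  expect_equal(allpos$TP + allpos$TN + allpos$FN, 0L)
  expect_error(confusion_counts("a", c("a", "b"), "a"), "equal length")
})

test_that("ACC, PPV and TPR follow their formulas; zero denominators are NA", {
  truth <- rep(c("+", "-"), c(11, 9))
  pred <- rep(c("+", "-", "+", "-"), c(9, 2, 1, 8))
  m <- classification_metrics(confusion_counts(truth, pred, "+"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)

  perfect <- classification_metrics(confusion_counts(truth, truth, "+"))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall),
               c(1, 1, 1))

  # nothing predicted positive: precision undefined, accuracy still fine
  expect_warning(
    none <- classification_metrics(
      confusion_counts(c("+", "-"), c("-", "-"), "+")),
    "precision undefined")
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 0.5)
})

test_that("metrics always reproduce from their own confusion counts", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    truth <- sample(c("p", "n"), n, replace = TRUE)
    pred <- sample(c("p", "n"), n, replace = TRUE)
    cc <- confusion_counts(truth, pred, "p")
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    m <- suppressWarnings(classification_metrics(cc))
    expect_equal(m$accuracy, (cc$TP + cc$TN) / (cc$P + cc$N))
    if (!is.na(m$precision)) expect_equal(m$precision, cc$TP / (cc$TP + cc$FP))
    if (!is.na(m$recall)) expect_equal(m$recall, cc$TP / (cc$TP + cc$FN))
  }
})

test_that("k-fold indices partition 1..n into near-equal seeded folds", {
  f10 <- kfold_indices(10, 5, seed = 1)
  expect_equal(unname(lengths(f10)), rep(2L, 5))
  f11 <- kfold_indices(11, 5, seed = 1)
  expect_equal(sort(unname(lengths(f11)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(f11), 1:11)
  expect_identical(kfold_indices(11, 5, seed = 1), f11)
  expect_error(kfold_indices(4, 5, seed = 1), "k")
  expect_error(kfold_indices(10, 1, seed = 1), "k")
})

test_that("stratified folds preserve class balance and name tiny classes", {
  labels <- rep(c("a", "b", "c"), c(20, 15, 10))
  folds <- stratified_kfold_indices(labels, 5, seed = 2)
  expect_setequal(unlist(folds), seq_along(labels))
  for (f in folds) {
    expect_equal(sum(labels[f] == "a"), 4L)
    expect_equal(sum(labels[f] == "b"), 3L)
    expect_equal(sum(labels[f] == "c"), 2L)
  }
  expect_error(stratified_kfold_indices(c("a", "a", "b"), 2, seed = 1),
               "class 'b'")
})

test_that("ROC/AUC matches exhaustive pair counting, including ties", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$auc, 0.5)

  scores <- c(0.9, 0.8, 0.35, 0.4)
  truth <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(scores, truth)$auc, auc_bruteforce(scores, truth))

  set.seed(99)
  for (i in 1:10) {
    n <- sample(8:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
    scores <- round(rnorm(n, mean = truth), 1)  # rounding forces ties
    expect_equal(roc_auc(scores, truth)$auc, auc_bruteforce(scores, truth),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC curves run monotonically from (0,0) to (1,1)", {
  set.seed(7)
  truth <- rep(c(TRUE, FALSE), 15)
  scores <- rnorm(30, mean = truth)
  r <- roc_auc(scores, truth)
  pts <- r$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  # AUC is the trapezoidal area under the curve
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
})

test_that("macro one-vs-rest ROC reduces to the binary ROC for two classes", {
  set.seed(17)
  truth <- rep(c("a", "b"), 20)
  z <- rnorm(40, mean = ifelse(truth == "b", 1, -1))
  scores <- cbind(a = -z, b = z)
  rr <- roc_ovr(scores, truth)
  expect_equal(rr$macro_auc, roc_auc(z, truth == "b")$auc)
})

test_that("cross-validation runs the protocol and reports one row per fold", {
  co <- generate_corpus(class_specs(n_docs = 15),
                        generator_config(seed = 4, mean_length = 60))
  res <- cross_validate(co, "nb", k = 3, repeats = 2, seed = 5)
  expect_equal(nrow(res$folds), 6L)
  expect_equal(res$mean_accuracy, mean(res$folds$accuracy))
  expect_equal(res$seeds, 5:6)
  expect_true(all(res$folds$accuracy >= 0 & res$folds$accuracy <= 1))
  # reproducibility of the whole protocol
  res2 <- cross_validate(co, "nb", k = 3, repeats = 2, seed = 5)
  expect_identical(res$folds, res2$folds)
  expect_error(cross_validate(co, "nb", k = 20, repeats = 1, seed = 1),
               "fewer than k")
})
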