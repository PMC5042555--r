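make_xy <- function(blobs) {
  list(X = Matrix::Matrix(blobs$X, sparse = TRUE),
       y = ifelse(blobs$labels == "c2", 1, -1))
}

test_that("naive Bayes priors, smoothing and posteriors behave", {
  X <- Matrix::sparseMatrix(i = 1:4, j = c(1, 2, 3, 3), x = c(2, 1, 3, 1),
                            dims = c(4, 3))
  y <- c("a", "a", "b", "b")
  m <- train_naive_bayes(X, y, lambda = 1)
  expect_equal(unname(m$log_prior), rep(log(0.5), 2))
  # term 3 never occurs in class a but stays strictly positive via smoothing
  expect_true(all(is.finite(m$log_lik)))
  expect_gt(exp(m$log_lik["a", 3]), 0)
  # per-class likelihoods are normalized distributions
  expect_equal(unname(rowSums(exp(m$log_lik))), c(1, 1), tolerance = 1e-12)

  pred <- nb_predict(m, Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                             dims = c(1, 3)))
  expect_equal(unname(rowSums(pred$posterior)), 1, tolerance = 1e-12)
  # all-zero vector falls back to the priors (tie -> first class)
  zero <- nb_predict(m, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(1, 3)))
  expect_equal(zero$label, "a")
  expect_error(nb_predict(m, matrix(0, 1, 5)), "dimension mismatch")
  expect_error(train_naive_bayes(X, rep("a", 4)), "2 classes")
})

test_that("naive Bayes equals exhaustive enumeration on a toy corpus", {
  # 2 classes, 3 terms, 6 documents, TF-IDF-like fractional values
  X <- matrix(c(2.0, 0.5, 0,
                1.5, 0,   0,
                2.5, 1.0, 0,
                0,   2.0, 1.5,
                0.5, 1.5, 2.0,
                0,   1.0, 1.0), nrow = 6, byrow = TRUE)
  y <- c("x", "x", "x", "y", "y", "y")
  m <- train_naive_bayes(Matrix::Matrix(X, sparse = TRUE), y, lambda = 1)
  probes <- list(c(3, 1, 0), c(0, 1, 3), c(1, 1, 1), c(0.2, 0, 1.4))
  for (p in probes) {
    oracle <- nb_enum_oracle(X, y, lambda = 1, probe = p)
    got <- nb_predict(m, matrix(p, nrow = 1))
    expect_equal(got$label, oracle$label)
    expect_equal(unname(got$log_joint[1, ]), unname(oracle$log_joint),
                 tolerance = 1e-10)
    expect_equal(unname(got$posterior[1, ]), unname(oracle$posterior),
                 tolerance = 1e-10)
  }
})

test_that("sigmoid is stable, monotone and hits its anchor points", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  z <- seq(-20, 20, length.out = 101)
  expect_true(all(diff(sigmoid(z)) > 0))
  expect_true(all(sigmoid(c(-1e3, 1e3)) >= 0 & sigmoid(c(-1e3, 1e3)) <= 1))
})

test_that("hinge SVM separates Gaussian blobs perfectly without regularization", {
  xy <- make_xy(generate_blobs(n_per_class = 50, sigma = 0.3, seed = 11))
  cfg <- train_config(reg_param = 0, regularizer = "none", seed = 1)
  m <- train_linear_sgd(xy$X, xy$y, loss = "hinge", config = cfg)
  z <- decision_score(m, xy$X)
  expect_true(all(sign(z) == xy$y))
})

test_that("L2 regularization shrinks the weight norm", {
  xy <- make_xy(generate_blobs(n_per_class = 50, sigma = 0.3, seed = 11))
  m0 <- train_linear_sgd(xy$X, xy$y, "hinge",
                         train_config(reg_param = 0, regularizer = "l2"))
  m10 <- train_linear_sgd(xy$X, xy$y, "hinge",
                          train_config(reg_param = 10, regularizer = "l2"))
  expect_lt(sqrt(sum(m10$w^2)), sqrt(sum(m0$w^2)))
})

test_that("the logistic loss at w = 0 is log(2)", {
  xy <- make_xy(generate_blobs(n_per_class = 10, sigma = 0.3, seed = 5))
  # a vanishing step keeps w at (numerically) zero through the first epoch
  m <- train_linear_sgd(xy$X, xy$y, "logistic",
                        train_config(iterations = 1, step_size = 1e-12,
                                     reg_param = 0, regularizer = "none"))
  expect_equal(m$objective[1], log(2), tolerance = 1e-9)
})

test_that("the regularized objective decreases on a convex toy problem", {
  xy <- make_xy(generate_blobs(n_per_class = 50, sigma = 0.3, seed = 3))
  for (loss in c("hinge", "logistic")) {
    m <- train_linear_sgd(xy$X, xy$y, loss, train_config())
    obj <- m$objective
    expect_lt(obj[length(obj)], obj[1])
    # monotone non-increasing up to a small tolerance once steps decay
    expect_true(all(diff(obj[10:length(obj)]) < 1e-3))
  }
})

test_that("training is bit-reproducible under a fixed configuration", {
  xy <- make_xy(generate_blobs(n_per_class = 30, sigma = 0.5, seed = 9))
  cfg <- train_config(seed = 42, minibatch_fraction = 0.5)
  m1 <- train_linear_sgd(xy$X, xy$y, "logistic", cfg)
  m2 <- train_linear_sgd(xy$X, xy$y, "logistic", cfg)
  expect_identical(m1$w, m2$w)
})

test_that("training rejects degenerate input", {
  xy <- make_xy(generate_blobs(n_per_class = 10, seed = 2))
  expect_error(train_linear_sgd(xy$X, rep(1, nrow(xy$X)), "hinge"),
               "single class")
  expect_error(train_linear_sgd(xy$X, xy$y * 2, "hinge"), "-1/\\+1")
  Xbad <- as.matrix(xy$X)
  Xbad[1, 1] <- NA
  expect_error(train_linear_sgd(Xbad, xy$y, "hinge"), "non-finite")
})

test_that("decision scores are plain inner products", {
  m <- structure(list(w = c(1, 2), loss = "hinge", regularizer = "none",
                      reg_param = 0, positive_class = "+1",
                      negative_class = "-1", d = 2L),
                 class = "linear_model")
  expect_equal(decision_score(m, matrix(c(3, 0.5), nrow = 1)), 4)
  expect_equal(decision_score(m, matrix(c(2, -1), nrow = 1)), 0)  # orthogonal
  m$w <- c(0, 0)
  expect_equal(decision_score(m, matrix(c(5, 5), nrow = 1)), 0)
  expect_error(decision_score(m, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("binary prediction thresholds at z > 0 with ties to the pivot", {
  m <- structure(list(w = c(1, 0), loss = "logistic", regularizer = "none",
                      reg_param = 0, positive_class = "pos",
                      negative_class = "neg", d = 2L),
                 class = "linear_model")
  tie <- predict_binary(m, matrix(c(0, 7), nrow = 1))
  expect_equal(tie$label, "neg")
  up <- predict_binary(m, matrix(c(2, 0), nrow = 1))
  expect_equal(up$label, "pos")
  expect_equal(up$probability, sigmoid(2))
  m$loss <- "hinge"
  down <- predict_binary(m, matrix(c(-0.1, 0), nrow = 1))
  expect_equal(down$label, "neg")
  expect_null(down$probability)
})

test_that("one-vs-rest agrees with the lone binary model on two classes", {
  blobs <- generate_blobs(n_per_class = 40, sigma = 0.4, seed = 21)
  X <- Matrix::Matrix(blobs$X, sparse = TRUE)
  cfg <- train_config(seed = 1)
  ovr <- ovr_train(X, blobs$labels, loss = "hinge", config = cfg)
  bin <- train_linear_sgd(X, ifelse(blobs$labels == "c2", 1, -1), "hinge",
                          config = cfg, positive_class = "c2",
                          negative_class = "c1")
  probes <- X[seq(1, nrow(X), by = 7), ]
  ovr_lab <- ovr_predict(ovr, probes)$label
  z <- decision_score(bin, probes)
  bin_lab <- ifelse(z > 0, "c2", "c1")
  expect_equal(ovr_lab, bin_lab)
})

test_that("one-vs-rest separates three synthetic classes and breaks ties lexicographically", {
  blobs <- generate_blobs(n_per_class = 40,
                          means = rbind(c(-3, 0), c(3, 0), c(0, 3)),
                          sigma = 0.3, seed = 13)
  X <- Matrix::Matrix(blobs$X, sparse = TRUE)
  ovr <- ovr_train(X, blobs$labels, loss = "logistic",
                   config = train_config(seed = 1))
  expect_equal(ovr_predict(ovr, X)$label, blobs$labels)
  # all-zero probe scores 0 for every class -> smallest label wins
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1, 2))
  # zero weights force an exact tie
  tied <- ovr
  for (cl in tied$classes) tied$models[[cl]]$w <- c(0, 0)
  expect_equal(ovr_predict(tied, zero)$label, "c1")
  expect_error(ovr_train(X, rep("one", nrow(X))), "2 classes")
})

test_that("SGD logistic regression tracks the glmnet solution on blobs", {
  skip_if_not_installed("glmnet")
  blobs <- generate_blobs(n_per_class = 50, sigma = 0.6, seed = 31)
  X <- blobs$X
  y <- ifelse(blobs$labels == "c2", 1, -1)
  m <- train_linear_sgd(Matrix::Matrix(X, sparse = TRUE), y, "logistic",
                        train_config(reg_param = 0.01, regularizer = "l2"))
  g <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                      lambda = 0.01, intercept = FALSE, standardize = FALSE)
  ours <- sign(decision_score(m, X))
  theirs <- sign(as.numeric(X %*% as.numeric(g$beta)))
  expect_gt(mean(ours == theirs), 0.95)
})
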