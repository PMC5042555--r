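#' Training configuration for the linear classifiers
#'
#' Defaults pin the long-documented Spark MLlib 1.x defaults for these
#' components: 100 full-batch subgradient iterations, step size 1.0 decayed
#' as `1/sqrt(t)`, regularization parameter `a = 0.01`, L2 penalty, and
#' Laplace smoothing `lambda = 1` for naive Bayes.
#'
#' @param iterations number of subgradient iterations (>= 1).
#' @param step_size initial step size (> 0); the step at iteration `t` is
#'   `step_size / sqrt(t)`.
#' @param reg_param regularization parameter `a >= 0` multiplying the
#'   penalty `R(w)` in the objective `f(w) = a R(w) + mean loss`.
#' @param regularizer one of `"l2"` (`R(w) = ||w||_2^2 / 2`), `"l1"`
#'   (`R(w) = ||w||_1`) or `"none"`.
#' @param seed integer seed controlling any stochastic subsampling.
#' @param minibatch_fraction fraction of the training set sampled per
#'   iteration; 1 (default) uses the full batch deterministically.
#' @param lambda Laplace smoothing for naive Bayes (> 0).
#' @return list of class `train_config`.
#' @export
train_config <- function(iterations = 100L, step_size = 1.0,
                         reg_param = 0.01,
                         regularizer = c("l2", "l1", "none"),
                         seed = 1L, minibatch_fraction = 1.0,
                         lambda = 1.0) {
  regularizer <- match.arg(regularizer)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (step_size <= 0) stop("`step_size` must be > 0", call. = FALSE)
  if (reg_param < 0) stop("`reg_param` must be >= 0", call. = FALSE)
  if (minibatch_fraction <= 0 || minibatch_fraction > 1) {
    stop("`minibatch_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  structure(list(iterations = as.integer(iterations), step_size = step_size,
                 reg_param = reg_param, regularizer = regularizer,
                 seed = as.integer(seed),
                 minibatch_fraction = minibatch_fraction, lambda = lambda),
            class = "train_config")
}

#' Logistic (sigmoid) function
#'
#' `f(z) = 1 / (1 + exp(-z))`, evaluated in a numerically stable form so
#' that extreme scores do not overflow.
#'
#' @param z numeric vector of decision scores `z = w'x`.
#' @return probabilities in (0, 1).
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(z) {
  out <- ifelse(z >= 0, 1 / (1 + exp(-z)), {
    e <- exp(z)
    e / (1 + e)
  })
  as.numeric(out)
}

.as_row_matrix <- function(x, d) {
  if (inherits(x, "sparseVector")) {
    x <- Matrix::sparseMatrix(i = rep(1L, length(x@i)), j = x@i, x = x@x,
                              dims = c(1L, x@length))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != d) {
    stop("feature dimension mismatch: model has ", d, ", input has ",
         ncol(x), call. = FALSE)
  }
  x
}

# ---- multinomial naive Bayes ------------------------------------------------

#' Train a multinomial naive Bayes classifier
#'
#' Assumes every pair of features is independent given the class. The TF-IDF
#' feature values serve as pseudo-counts: the likelihood of term `t` under
#' class `c` is proportional to the summed feature mass of `t` in class `c`
#' plus the Laplace smoothing `lambda`; priors are class proportions.
#'
#' @param X sparse or dense document-term matrix (rows = documents).
#' @param y character vector of class labels, one per row; every class must
#'   have at least one example.
#' @param lambda additive (Laplace) smoothing, > 0. Default 1.
#' @return object of class `nb_model` with `classes`, `log_prior`,
#'   `log_lik` (classes x terms matrix), `lambda`.
#' @export
train_naive_bayes <- function(X, y, lambda = 1.0) {
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(y)) stop("labels must not be missing", call. = FALSE)
  classes <- sort(unique(y), method = "radix")
  if (length(classes) < 2L) {
    stop("need at least 2 classes with examples", call. = FALSE)
  }
  d <- ncol(X)
  log_prior <- log(as.numeric(table(factor(y, classes))) / length(y))
  log_lik <- matrix(NA_real_, nrow = length(classes), ncol = d,
                    dimnames = list(classes, colnames(X)))
  for (k in seq_along(classes)) {
    s <- Matrix::colSums(X[y == classes[k], , drop = FALSE])
    log_lik[k, ] <- log(s + lambda) - log(sum(s) + lambda * d)
  }
  names(log_prior) <- classes
  structure(list(classes = classes, log_prior = log_prior, log_lik = log_lik,
                 lambda = lambda, d = d),
            class = "nb_model")
}

#' Predict with a naive Bayes model
#'
#' Scores each class as `log prior + sum_t x_t * log lik(t | class)` and
#' returns the argmax label (ties go to the lexicographically smallest class)
#' together with normalized posteriors.
#'
#' @param model an `nb_model`.
#' @param x feature vector or document-term matrix with matching dimension.
#' @return list with `label` (character vector), `posterior` (rows sum to 1)
#'   and `log_joint` (unnormalized class scores).
#' @export
nb_predict <- function(model, x) {
  stopifnot(inherits(model, "nb_model"))
  X <- .as_row_matrix(x, model$d)
  joint <- as.matrix(X %*% t(model$log_lik))
  joint <- sweep(joint, 2L, model$log_prior, `+`)
  # normalize with log-sum-exp
  mx <- apply(joint, 1L, max)
  post <- exp(joint - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  label <- model$classes[max.col(joint, ties.method = "first")]
  list(label = label, posterior = post, log_joint = joint)
}

# ---- linear models by regularized subgradient descent -----------------------

.loss_grad <- function(loss, X, y, w) {
  # subgradient of the mean loss over the batch
  margins <- y * as.numeric(X %*% w)
  n <- length(y)
  if (loss == "hinge") {
    active <- margins < 1
    if (!any(active)) return(numeric(length(w)))
    as.numeric(Matrix::crossprod(X[active, , drop = FALSE],
                                 -y[active])) / n
  } else {
    coef <- -y * sigmoid(-margins)
    as.numeric(Matrix::crossprod(X, coef)) / n
  }
}

.mean_loss <- function(loss, X, y, w) {
  margins <- y * as.numeric(X %*% w)
  if (loss == "hinge") {
    mean(pmax(0, 1 - margins))
  } else {
    # log(1 + exp(-m)) computed stably
    m <- -margins
    mean(ifelse(m > 30, m, log1p(exp(m))))
  }
}

.reg_value <- function(regularizer, w) {
  switch(regularizer,
         none = 0,
         l1 = sum(abs(w)),
         l2 = 0.5 * sum(w^2))
}

#' Train a linear classifier by regularized subgradient descent
#'
#' Minimizes the convex objective
#' `f(w) = a R(w) + (1/n) sum_i L(w; x_i, y_i)` where `L` is the hinge loss
#' `max(0, 1 - y w'x)` (linear SVM) or the logistic loss
#' `log(1 + exp(-y w'x))`, and `R(w)` is none, `||w||_1` or `||w||_2^2 / 2`.
#' The step at iteration `t` is `step_size / sqrt(t)`; the L2 penalty enters
#' the subgradient, while L1 is applied by soft-thresholding after each step.
#' Weights start at zero, so identical data and configuration reproduce
#' bit-identical weights.
#'
#' @param X document-term matrix (rows = training instances).
#' @param y labels in `{-1, +1}`; both classes must be present.
#' @param loss `"hinge"` or `"logistic"`.
#' @param config a [train_config()].
#' @param positive_class,negative_class optional label strings attached to
#'   the model for reporting.
#' @return object of class `linear_model` with weights `w`, the per-iteration
#'   `objective` trace, and the training metadata.
#' @export
train_linear_sgd <- function(X, y, loss = c("hinge", "logistic"),
                             config = train_config(),
                             positive_class = "+1", negative_class = "-1") {
  loss <- match.arg(loss)
  stopifnot(inherits(config, "train_config"))
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be encoded as -1/+1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  vals <- if (methods::is(X, "sparseMatrix")) X@x else as.numeric(X)
  if (any(!is.finite(vals))) {
    stop("non-finite feature values", call. = FALSE)
  }
  d <- ncol(X)
  w <- numeric(d)
  a <- config$reg_param
  objective <- numeric(config$iterations)
  set.seed(config$seed)
  n <- length(y)
  for (t in seq_len(config$iterations)) {
    if (config$minibatch_fraction < 1) {
      idx <- sample.int(n, max(1L, round(n * config$minibatch_fraction)))
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
    } else {
      Xb <- X
      yb <- y
    }
    g <- .loss_grad(loss, Xb, yb, w)
    gamma <- config$step_size / sqrt(t)
    if (config$regularizer == "l2") {
      w <- w - gamma * (g + a * w)
    } else if (config$regularizer == "l1") {
      w <- w - gamma * g
      w <- sign(w) * pmax(abs(w) - gamma * a, 0)
    } else {
      w <- w - gamma * g
    }
    objective[t] <- a * .reg_value(config$regularizer, w) +
      .mean_loss(loss, X, y, w)
  }
  structure(list(w = w, loss = loss, regularizer = config$regularizer,
                 reg_param = a, config = config, objective = objective,
                 positive_class = positive_class,
                 negative_class = negative_class, d = d),
            class = "linear_model")
}

#' Decision score of a linear model
#'
#' Returns the inner product `z = w'x` for each input row.
#'
#' @param model a `linear_model`.
#' @param x feature vector or matrix with matching dimension.
#' @return numeric vector of scores.
#' @export
decision_score <- function(model, x) {
  stopifnot(inherits(model, "linear_model"))
  X <- .as_row_matrix(x, model$d)
  as.numeric(X %*% model$w)
}

#' Binary prediction from a linear model
#'
#' The outcome is positive iff `z = w'x > 0`; for the logistic loss this is
#' equivalent to thresholding the class probability `sigmoid(z)` at 0.5. An
#' exact tie (`z = 0`) resolves to the negative (pivot) class.
#'
#' @param model a `linear_model`.
#' @param x feature vector or matrix.
#' @return list with `label` (character), `score` (`z`) and, for logistic
#'   models, `probability`; for hinge models `probability` is `NULL`.
#' @export
predict_binary <- function(model, x) {
  z <- decision_score(model, x)
  positive <- z > 0
  label <- ifelse(positive, model$positive_class, model$negative_class)
  prob <- if (model$loss == "logistic") sigmoid(z) else NULL
  list(label = label, score = z, probability = prob)
}

# ---- one-vs-rest multiclass -------------------------------------------------

#' Train one-vs-rest linear classifiers
#'
#' Trains one binary model per class (that class positive, all others
#' negative); prediction takes the class with the largest decision score,
#' with exact ties going to the lexicographically smallest label.
#'
#' @param X document-term matrix.
#' @param y character class labels (at least 2 distinct).
#' @param loss `"hinge"` or `"logistic"`.
#' @param config a [train_config()].
#' @return object of class `ovr_model`: ordered `classes` plus one
#'   `linear_model` per class.
#' @export
ovr_train <- function(X, y, loss = c("hinge", "logistic"),
                      config = train_config()) {
  loss <- match.arg(loss)
  y <- as.character(y)
  classes <- sort(unique(y), method = "radix")
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  models <- lapply(classes, function(cl) {
    yb <- ifelse(y == cl, 1, -1)
    train_linear_sgd(X, yb, loss = loss, config = config,
                     positive_class = cl, negative_class = ".rest")
  })
  names(models) <- classes
  structure(list(classes = classes, models = models, loss = loss,
                 d = ncol(X)),
            class = "ovr_model")
}

#' @rdname ovr_train
#' @param model an `ovr_model`.
#' @param x feature vector or matrix.
#' @return for `ovr_predict`: list with `label` and the per-class `scores`
#'   matrix.
#' @export
ovr_predict <- function(model, x) {
  stopifnot(inherits(model, "ovr_model"))
  X <- .as_row_matrix(x, model$d)
  W <- vapply(model$models, `[[`, numeric(model$d), "w")
  scores <- as.matrix(X %*% W)
  colnames(scores) <- model$classes
  label <- model$classes[max.col(scores, ties.method = "first")]
  list(label = label, scores = scores)
}
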