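# Classifier stable: gradient boosting (xgboost), RBF support vector
# machine, k-nearest neighbors, L2-regularized logistic regression, and a
# single-hidden-layer perceptron. Every model exposes a continuous class-1
# score for AUROC alongside hard 0/1 predictions.

#' Specify a classifier
#'
#' @param name One of `"GB"`, `"SVM"`, `"KNN"`, `"LR"`, `"MLP"`.
#' @param ... Hyperparameter overrides. Defaults: GB `nrounds = 50`,
#'   `max_depth = 3`, `eta = 0.3`; SVM `cost = 1`, `gamma = NULL` (1/p);
#'   KNN `k = 5`, `select_k = FALSE`, `k_max = 20`; LR `lambda = 0.01`;
#'   MLP `size = 10`, `decay = 1e-3`, `maxit = 200`.
#' @param seed Seed used wherever the learner is stochastic.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name = c("KNN", "GB", "SVM", "LR", "MLP"), ...,
                            seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    GB = list(nrounds = 50, max_depth = 3, eta = 0.3),
    SVM = list(cost = 1, gamma = NULL),
    KNN = list(k = 5, select_k = FALSE, k_max = 20),
    LR = list(lambda = 0.01),
    MLP = list(size = 10, decay = 1e-3, maxit = 200)
  )
  hyper <- utils::modifyList(defaults, list(...))
  if (name == "KNN" && !(hyper$k >= 1 && hyper$k <= 20)) {
    stopf("KNN k must lie in [1, 20]")
  }
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier
#'
#' Deterministic for a fixed spec seed. KNN with `select_k = TRUE` first
#' chooses k by inner cross-validation via [select_knn_k()].
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (rows = instances).
#' @param y 0/1 labels.
#' @return A fitted `dreamsift_classifier` handle.
#' @export
train_classifier <- function(spec, X, y) {
  if (!inherits(spec, "classifier_spec")) stopf("'spec' must be a classifier_spec")
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("rows of X must match length of y")
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  h <- spec$hyper
  fit <- with_seed(spec$seed, switch(spec$name,
    KNN = {
      k <- h$k
      if (isTRUE(h$select_k)) k <- select_knn_k(X, y, k_max = h$k_max,
                                                seed = spec$seed)
      list(X = X, y = y, k = k)
    },
    GB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = h$max_depth,
                    eta = h$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = h$nrounds, verbose = 0
    ),
    SVM = e1071::svm(
      x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
      cost = h$cost, gamma = h$gamma %||% (1 / ncol(X)), scale = FALSE
    ),
    LR = glmnet::glmnet(
      x = X, y = factor(y, levels = c(0, 1)), family = "binomial",
      alpha = 0, lambda = h$lambda, standardize = FALSE
    ),
    MLP = nnet::nnet(
      x = X, y = y, size = h$size, decay = h$decay, maxit = h$maxit,
      entropy = TRUE, trace = FALSE, MaxNWts = 1e6
    )
  ))
  structure(list(name = spec$name, fit = fit, spec = spec, p = ncol(X)),
            class = "dreamsift_classifier")
}

#' Predict with a fitted classifier
#'
#' @param model A `dreamsift_classifier` from [train_classifier()].
#' @param X Numeric feature matrix.
#' @return List with `pred` (0/1 vector) and `score` (continuous class-1
#'   score; for KNN the neighbor vote fraction).
#' @export
predict_classifier <- function(model, X) {
  if (!inherits(model, "dreamsift_classifier")) stopf("'model' must be fitted")
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != model$p) stopf("feature dimension mismatch")
  switch(model$name,
    KNN = with_seed(model$spec$seed, {
      out <- class::knn(model$fit$X, X, factor(model$fit$y, levels = c(0, 1)),
                        k = model$fit$k, prob = TRUE)
      p_win <- attr(out, "prob")
      pred <- as.integer(as.character(out))
      list(pred = pred, score = ifelse(pred == 1, p_win, 1 - p_win))
    }),
    GB = {
      s <- stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))
      list(pred = as.integer(s >= 0.5), score = as.numeric(s))
    },
    SVM = {
      pr <- stats::predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1]
      # decision values are signed toward the first factor level ("0")
      score <- if (grepl("^0/", colnames(attr(pr, "decision.values"))[1])) -dv else dv
      list(pred = as.integer(as.character(pr)), score = as.numeric(score))
    },
    LR = {
      s <- as.numeric(stats::predict(model$fit, newx = X, type = "response"))
      list(pred = as.integer(s >= 0.5), score = s)
    },
    MLP = {
      s <- as.numeric(stats::predict(model$fit, X))
      list(pred = as.integer(s >= 0.5), score = s)
    }
  )
}

#' Select k for KNN by inner cross-validation
#'
#' Evaluates `k = 1..k_max` by stratified inner cross-validation and
#' returns the k maximizing mean accuracy; ties go to the smaller k.
#'
#' @param X_train Numeric feature matrix.
#' @param y_train 0/1 labels.
#' @param k_max Largest k tried (default 20).
#' @param inner_folds Number of inner folds (default 5).
#' @param seed Seed for the inner fold assignment and vote tie-breaks.
#' @return The chosen k.
#' @export
select_knn_k <- function(X_train, y_train, k_max = 20, inner_folds = 5,
                         seed = 1L) {
  if (!is_count(k_max)) stopf("'k_max' must be a positive integer")
  n <- nrow(X_train)
  if (n < inner_folds) stopf("fewer instances (%d) than inner folds (%d)", n, inner_folds)
  with_seed(seed, {
    fold <- integer(n)
    for (cl in unique(y_train)) {
      idx <- sample(which(y_train == cl))
      fold[idx] <- rep_len(seq_len(inner_folds), length(idx))
    }
    acc <- numeric(k_max)
    for (k in seq_len(k_max)) {
      correct <- 0
      for (f in seq_len(inner_folds)) {
        te <- which(fold == f)
        tr <- which(fold != f)
        if (length(te) == 0 || length(unique(y_train[tr])) < 2) next
        kk <- min(k, length(tr))
        pred <- class::knn(X_train[tr, , drop = FALSE],
                           X_train[te, , drop = FALSE],
                           factor(y_train[tr], levels = c(0, 1)), k = kk)
        correct <- correct + sum(as.integer(as.character(pred)) == y_train[te])
      }
      acc[k] <- correct / n
    }
    which.max(acc)  # which.max returns the first (smallest) maximizer
  })
}
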