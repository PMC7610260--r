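#' Classical comparison classifiers
#'
#' Fits one of the standard baselines — LASSO-penalized logistic
#' regression, random forest, or a support vector machine — as a
#' comparison point for the neural classifier, and returns continuous case
#' scores. These are established methods, so the fits delegate to glmnet,
#' randomForest and e1071 respectively; hyperparameters are chosen by
#' internal cross-validation on the training data (LASSO penalty path via
#' `cv.glmnet`; SVM cost over a small grid by stratified 5-fold CV).
#' `"opls_da"` routes to the package's own [fit_opls_da()].
#'
#' @param name one of `"lasso"`, `"random_forest"`, `"svm"`, `"opls_da"`.
#' @param X training feature matrix, samples x features.
#' @param y binary training labels (0/1).
#' @param hyper optional named list of hyperparameter overrides:
#'   `lambda` (lasso), `ntree` (random forest), `cost`/`kernel` (svm),
#'   `n_orthogonal` (opls_da).
#' @param seed integer seed; fits are deterministic given it.
#' @return A `baseline_model` with elements `name`, `fit`, and
#'   `scores` (case scores on the training data). Use [predict()] for new
#'   samples.
#' @export
run_baseline <- function(name, X, y, hyper = list(), seed = 1L) {
  valid <- c("lasso", "random_forest", "svm", "opls_da")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown baseline '", paste(name, collapse = ","),
         "'; valid options: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("shape error: length(y) != nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L) stop("fit error: single-class labels", call. = FALSE)
  set.seed(seed)
  fit <- switch(
    name,
    lasso = {
      if (!is.null(hyper$lambda)) {
        glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = hyper$lambda)
      } else {
        glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1, nfolds = 5)
      }
    },
    random_forest = {
      ntree <- if (is.null(hyper$ntree)) 500 else hyper$ntree
      randomForest::randomForest(X, factor(y, levels = c(0, 1)), ntree = ntree)
    },
    svm = {
      kernel <- if (is.null(hyper$kernel)) "radial" else hyper$kernel
      cost <- hyper$cost
      if (is.null(cost)) {
        grid <- c(0.1, 1, 10)
        folds <- stratified_kfold(y, k = 5, seed = seed)
        cv_auc <- vapply(grid, function(cc) {
          mean(vapply(folds, function(test) {
            tr <- setdiff(seq_along(y), test)
            m <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                            kernel = kernel, cost = cc, probability = FALSE)
            dv <- attr(stats::predict(m, X[test, , drop = FALSE],
                                      decision.values = TRUE), "decision.values")
            sc <- svm_case_scores(dv)
            auc(sc, y[test])
          }, numeric(1)))
        }, numeric(1))
        cost <- grid[which.max(cv_auc)]
      }
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = kernel, cost = cost,
                 probability = FALSE)
    },
    opls_da = {
      no <- if (is.null(hyper$n_orthogonal)) 1L else hyper$n_orthogonal
      suppressWarnings(fit_opls_da(X, y, n_orthogonal = no))
    }
  )
  model <- structure(list(name = name, fit = fit, seed = as.integer(seed)),
                     class = "baseline_model")
  model$scores <- predict(model, X)
  model
}

# decision values are signed toward the first factor level; orient to case
svm_case_scores <- function(dv) {
  neg <- grepl("^0/", colnames(dv)[1])
  sc <- drop(dv)
  if (neg) -sc else sc
}

#' Case scores from a fitted baseline
#'
#' @param object a `baseline_model`.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return Numeric case-score vector (probabilities for lasso/random
#'   forest, decision values for SVM, projection scores for OPLS-DA).
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(
    object$name,
    lasso = {
      s <- if (inherits(object$fit, "cv.glmnet")) "lambda.min" else NULL
      drop(stats::predict(object$fit, newdata, s = s, type = "response"))
    },
    random_forest = {
      stats::predict(object$fit, newdata, type = "prob")[, "1"]
    },
    svm = {
      dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
                 "decision.values")
      neg <- grepl("^0/", colnames(dv)[1])
      sc <- drop(dv)
      if (neg) -sc else sc
    },
    opls_da = opls_predict(object$fit, newdata)
  )
}
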