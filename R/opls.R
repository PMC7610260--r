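#' Orthogonal partial least squares discriminant analysis (OPLS-DA)
#'
#' From-scratch OPLS-DA for a binary response. Predictors are centered and
#' unit-variance scaled and the class labels encoded as a centered +/-1
#' response. The fit repeatedly extracts the X-weight vector proportional
#' to `X'y`, removes (`deflates`) one y-orthogonal component at a time —
#' the part of each X-loading orthogonal to the predictive weight vector —
#' and finally fits a single predictive component on the deflated matrix.
#' By construction every orthogonal score has exactly zero sample
#' correlation with the response used in fitting. With `n_orthogonal = 0`
#' the model reduces to single-component PLS1.
#'
#' @param X numeric feature matrix, samples x features. Constant columns
#'   are dropped with a warning.
#' @param y binary labels (0/1 or two-level factor).
#' @param n_orthogonal number of y-orthogonal components to remove.
#' @return An `opls_model` holding the predictive weights/loadings, the
#'   per-component orthogonal weights/loadings, the y-loading and the
#'   centering/scaling vectors needed for out-of-sample projection.
#' @export
fit_opls_da <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) != 2L) stop("fit error: y must contain exactly two classes", call. = FALSE)
  if (length(y) != nrow(X)) stop("shape error: length(y) != nrow(X)", call. = FALSE)
  n_orthogonal <- check_count(n_orthogonal, "n_orthogonal", min = 0L)
  if (nrow(X) <= n_orthogonal + 1) {
    stop("fit error: need n_samples > n_orthogonal + 1", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < ncol(X)) {
    warning(sprintf("dropping %d constant feature column(s)", ncol(X) - length(keep)))
  }
  if (!length(keep)) stop("fit error: no non-constant features", call. = FALSE)
  mu <- colMeans(X[, keep, drop = FALSE])
  sd_ <- sds[keep]
  Xc <- sweep(sweep(X[, keep, drop = FALSE], 2, mu), 2, sd_, "/")
  yy <- ifelse(y == max(y), 1, -1)
  yy <- yy - mean(yy)

  W_o <- P_o <- NULL
  Xd <- Xc
  if (n_orthogonal > 0) {
    W_o <- matrix(0, length(keep), n_orthogonal)
    P_o <- matrix(0, length(keep), n_orthogonal)
    for (k in seq_len(n_orthogonal)) {
      w <- drop(crossprod(Xd, yy))
      w <- w / sqrt(sum(w^2))
      t_p <- drop(Xd %*% w)
      p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
      w_o <- p - drop(crossprod(w, p)) * w
      no <- sqrt(sum(w_o^2))
      if (no < 1e-12) {
        # no y-orthogonal variation left; stop deflating
        W_o <- W_o[, seq_len(k - 1L), drop = FALSE]
        P_o <- P_o[, seq_len(k - 1L), drop = FALSE]
        break
      }
      w_o <- w_o / no
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      W_o[, k] <- w_o
      P_o[, k] <- p_o
    }
  }
  w <- drop(crossprod(Xd, yy))
  w <- w / sqrt(sum(w^2))
  t_p <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(yy * t_p) / sum(t_p^2)

  structure(
    list(predictive_weights = w, predictive_loadings = p,
         orthogonal_weights = W_o, orthogonal_loadings = P_o,
         n_orthogonal = if (is.null(W_o)) 0L else ncol(W_o),
         y_loading = q, feature_means = mu, feature_sds = sd_,
         kept_columns = keep, n_features_in = ncol(X),
         scores = t_p * q),
    class = "opls_model"
  )
}

#' Project new samples through an OPLS-DA model
#'
#' Applies the stored centering/scaling, strips the stored orthogonal
#' components sequentially, and projects onto the predictive component.
#' Higher scores indicate the case class. Predicting on the training
#' matrix reproduces the in-fit scores.
#'
#' @param model an `opls_model`.
#' @param X feature matrix with the same columns as at fit time.
#' @return Numeric score vector.
#' @export
opls_predict <- function(model, X) {
  stopifnot(inherits(model, "opls_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features_in) {
    stop("shape error: feature count does not match fit", call. = FALSE)
  }
  Xc <- sweep(sweep(X[, model$kept_columns, drop = FALSE], 2,
                    model$feature_means), 2, model$feature_sds, "/")
  for (k in seq_len(model$n_orthogonal)) {
    t_o <- drop(Xc %*% model$orthogonal_weights[, k])
    Xc <- Xc - tcrossprod(t_o, model$orthogonal_loadings[, k])
  }
  drop(Xc %*% model$predictive_weights) * model$y_loading
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Evaluates candidate `n_orthogonal` values by stratified k-fold
#' out-of-fold AUC and returns the smallest value within one standard
#' error of the best.
#'
#' @param X,y as in [fit_opls_da()].
#' @param candidates integer vector of component counts.
#' @param k folds.
#' @param seed integer seed.
#' @return Selected `n_orthogonal`.
#' @export
select_n_orthogonal <- function(X, y, candidates = 0:3, k = 5, seed = 1L) {
  folds <- stratified_kfold(y, k = k, seed = seed)
  mean_auc <- vapply(candidates, function(no) {
    aucs <- vapply(folds, function(test) {
      train <- setdiff(seq_along(y), test)
      m <- suppressWarnings(fit_opls_da(X[train, , drop = FALSE], y[train], no))
      auc(opls_predict(m, X[test, , drop = FALSE]), y[test])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  candidates[which.max(mean_auc)]
}
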