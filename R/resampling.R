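#' Stratified k-fold partition
#'
#' Shuffles each class under the seed and deals samples round-robin into k
#' folds, so per-fold class counts differ from exact proportionality by at
#' most one sample.
#'
#' @param labels binary (or multi-class) label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of k disjoint integer index vectors covering all samples.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("fold error: class '%s' has fewer than k = %d members",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  }
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    # stagger the round-robin start per class so the leftover samples of
    # successive classes land in different folds, keeping overall fold
    # sizes within one of each other
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    offset <- (offset + length(idx)) %% k
  }
  lapply(folds, sort)
}

#' Cross-validated evaluation of a fit-and-score procedure
#'
#' Runs stratified k-fold cross-validation: `fit_score(X_train, y_train,
#' X_test)` must return case scores for the test rows. Metrics are
#' computed per fold and averaged (pooling the out-of-fold predictions is
#' available via `pool = TRUE`).
#'
#' @param fit_score function `(X_train, y_train, X_test) -> scores`.
#' @param X feature matrix.
#' @param y binary labels.
#' @param k folds.
#' @param seed integer seed (governs the fold split).
#' @param pool pool out-of-fold scores into one ROC instead of averaging
#'   per-fold metrics.
#' @return List with `mean_auc`, `fold_auc`, and (pooled mode) `scores`.
#' @export
cv_evaluate <- function(fit_score, X, y, k = 10, seed = 1L, pool = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- stratified_kfold(y, k = k, seed = seed)
  all_scores <- rep(NA_real_, length(y))
  fold_auc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(y), test)
    sc <- fit_score(X[train, , drop = FALSE], y[train], X[test, , drop = FALSE])
    all_scores[test] <- sc
    fold_auc[f] <- auc(sc, y[test])
  }
  out <- list(fold_auc = fold_auc,
              mean_auc = if (pool) auc(all_scores, y) else mean(fold_auc))
  if (pool) out$scores <- all_scores
  out
}

#' Label-permutation test for a classification statistic
#'
#' Refits under B uniformly permuted label vectors and reports the
#' add-one estimator `p = (1 + #permuted >= observed) / (B + 1)`, which is
#' never zero; with B = 999 the smallest attainable p is 0.001.
#'
#' @param fit_and_score function `(X, y) -> scalar statistic` (e.g. mean
#'   cross-validated AUC); larger = stronger signal.
#' @param X feature matrix.
#' @param y binary labels.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return List with `p_value`, `observed`, `permuted` (length B).
#' @export
permutation_test <- function(fit_and_score, X, y, B = 999, seed = 1L) {
  B <- check_count(B, "B")
  # all label permutations are drawn up front: fit_and_score is free to
  # seed the RNG internally (e.g. for CV folds) without tying the
  # permutation stream to its own
  set.seed(seed)
  perms <- lapply(seq_len(B), function(b) sample(y))
  observed <- fit_and_score(X, y)
  permuted <- vapply(perms, function(yp) fit_and_score(X, yp), numeric(1))
  list(p_value = (1 + sum(permuted >= observed)) / (B + 1),
       observed = observed, permuted = permuted)
}

#' Minimum sample size for a two-group comparison
#'
#' Normal-approximation two-sided two-sample formula:
#' `n_per_group = 2 * ((z_{1-alpha/2} + z_{power}) / d)^2`, rounded up;
#' returns the total over two equal groups.
#'
#' @param effect_size_d standardized mean difference (Cohen's d), > 0.
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @return List with `n_per_group` and `n_total`.
#' @export
min_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.9) {
  if (!(effect_size_d > 0)) stop_config("effect_size_d", "must be > 0")
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha", "must lie in (0, 1)")
  if (!(power > 0 && power < 1)) stop_config("power", "must lie in (0, 1)")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n_per <- ceiling(2 * ((z_a + z_b) / effect_size_d)^2)
  list(n_per_group = n_per, n_total = 2L * n_per)
}
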