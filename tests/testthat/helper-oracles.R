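# Independent brute-force oracles used to pin expected values.

# AUC by counting concordant case/control pairs (ties weighted 1/2)
pair_count_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(ctrls))
}

# exhaustive Youden scan over all candidate cuts, same tie-break contract:
# maximize J, then maximize specificity
brute_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(t = t, j = j, spec = spec)
    }
  }
  best$t
}

# single-component PLS1: NIPALS closed form on centered/scaled data
pls1_scores <- function(X_train, y_train, X_new) {
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, sd)
  keep <- sd_ > 0
  Xc <- sweep(sweep(X_train[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  yy <- ifelse(y_train == max(y_train), 1, -1)
  yy <- yy - mean(yy)
  w <- drop(crossprod(Xc, yy))
  w <- w / sqrt(sum(w^2))
  t_tr <- drop(Xc %*% w)
  q <- sum(yy * t_tr) / sum(t_tr^2)
  Xn <- sweep(sweep(X_new[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  drop(Xn %*% w) * q
}

# quick fit-and-score statistic for permutation tests: mean CV AUC of a
# difference-of-class-means linear scorer (cheap, deterministic given folds)
mean_diff_cv_auc <- function(X, y, k = 5, seed = 99) {
  cv <- cv_evaluate(function(Xtr, ytr, Xte) {
    w <- colMeans(Xtr[ytr == 1, , drop = FALSE]) -
      colMeans(Xtr[ytr == 0, , drop = FALSE])
    drop(Xte %*% w)
  }, X, y, k = k, seed = seed)
  cv$mean_auc
}

# small balanced Gaussian two-class dataset with separation d on every bin
toy_gaussian <- function(n_per = 50, p = 5, d = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = d), n_per, p))
  list(X = X, y = rep(c(0L, 1L), each = n_per))
}
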