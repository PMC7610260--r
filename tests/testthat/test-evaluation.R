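test_that("AUC equals the concordant-pair oracle, including ties", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), pair_count_auc(scores, labels))
  }
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("DeLong interval contains the point AUC and shrinks with n", {
  set.seed(2)
  mk <- function(n) {
    y <- rep(c(0L, 1L), each = n)
    s <- rnorm(2 * n, mean = y * 2)
    delong_ci(s, y)
  }
  small <- mk(50)
  big <- mk(500)
  expect_true(small$ci_low <= small$auc && small$auc <= small$ci_high)
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
  # perfect separation -> degenerate point interval with warning
  expect_warning(d <- delong_ci(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)),
                 "degenerate")
  expect_equal(c(d$ci_low, d$ci_high), c(1, 1))
})

test_that("DeLong CI and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(31)
  y <- rep(c(0L, 1L), each = 40)
  s1 <- rnorm(80, mean = y)
  s2 <- rnorm(80, mean = 0.5 * y)
  ci <- delong_ci(s1, y)
  r1 <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(c(ci$ci_low, ci$auc, ci$ci_high),
               as.numeric(pROC::ci.auc(r1, method = "delong")),
               tolerance = 1e-8)
  r2 <- pROC::roc(y, s2, quiet = TRUE, direction = "<")
  pt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(delong_test(s1, s2, y)$p_value, pt$p.value, tolerance = 1e-8)
})

test_that("identical score vectors give p = 1 in the paired test", {
  y <- rep(c(0L, 1L), each = 10)
  s <- rnorm(20)
  expect_equal(delong_test(s, s, y)$p_value, 1.0)
})

test_that("a discriminating model beats noise decisively in the paired test", {
  set.seed(41)
  y <- rep(c(0L, 1L), each = 100)
  good <- y + rnorm(200, sd = 0.1)
  noise <- rnorm(200)
  expect_lt(delong_test(good, noise, y)$p_value, 0.01)
})

test_that("Youden threshold matches the exhaustive-scan oracle with tie-break", {
  # worked instance: J = 0.5 tied; tie-break picks the higher-specificity cut
  thr <- youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_true(thr > 0.4 && thr < 0.8)
  cf <- confusion_at(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), thr)
  expect_equal(cf$specificity, 1.0)
  expect_equal(cf$sensitivity, 0.5)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    expect_equal(youden_threshold(scores, labels), brute_youden(scores, labels))
  }
})

test_that("confusion sentinels behave at infinite thresholds", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(confusion_at(s, y, -Inf), list(sensitivity = 1, specificity = 0))
  expect_equal(confusion_at(s, y, Inf), list(sensitivity = 0, specificity = 1))
  expect_equal(confusion_at(s, y, 0.5), list(sensitivity = 0.5, specificity = 1))
})

test_that("stratified folds partition the discovery cohort evenly", {
  y <- c(rep(0L, 137), rep(1L, 138))
  folds <- stratified_kfold(y, k = 10, seed = 2)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(27L, 28L)))
  for (f in folds) {
    tab <- table(y[f])
    expect_true(all(tab >= 13 & tab <= 14))
  }
  expect_setequal(unlist(folds), seq_along(y))
  expect_equal(sum(lengths(folds)), length(y))
  expect_identical(folds, stratified_kfold(y, k = 10, seed = 2))
  expect_error(stratified_kfold(c(rep(0, 30), 1, 1), k = 10), "fold error")
})

test_that("threshold transfers from discovery to validation unchanged", {
  set.seed(61)
  yd <- rep(c(0L, 1L), each = 30)
  yv <- rep(c(0L, 1L), each = 10)
  sd_ <- yd + rnorm(60, sd = 0.6)
  sv <- yv + rnorm(20, sd = 0.6)
  rep_ <- evaluate_split(sd_, yd, sv, yv)
  expect_equal(rep_$threshold[1], rep_$threshold[2])
  expect_equal(rep_$threshold[1], youden_threshold(sd_, yd))
  cf <- confusion_at(sv, yv, rep_$threshold[1])
  expect_equal(rep_$sensitivity[2], cf$sensitivity)
})

test_that("permutation p has the add-one floor and degenerate behavior", {
  # observed always exceeds permutations: cheap deterministic statistic
  to <- toy_gaussian(20, 3, d = 3, seed = 8)
  pt <- permutation_test(function(X, y) mean_diff_cv_auc(X, y, k = 4),
                         to$X, to$y, B = 999, seed = 5)
  expect_equal(pt$p_value, 0.001)
  expect_length(pt$permuted, 999)
  # B = 1 with permuted >= observed gives p = 1
  pt1 <- permutation_test(function(X, y) 0, to$X, to$y, B = 1, seed = 5)
  expect_equal(pt1$p_value, 1.0)
})

test_that("power analysis matches the closed-form normal approximation", {
  # back-solved effect size consistent with a printed minimum of 62
  res <- min_sample_size(0.695, alpha = 0.15, power = 0.9)
  expect_equal(res$n_total, 62L)
  by_hand <- ceiling(2 * ((qnorm(1 - 0.15 / 2) + qnorm(0.9)) / 0.695)^2)
  expect_equal(res$n_per_group, by_hand)
  # doubling d quarters n (up to ceiling)
  n1 <- min_sample_size(0.5, 0.05, 0.8)$n_per_group
  n2 <- min_sample_size(1.0, 0.05, 0.8)$n_per_group
  expect_lte(abs(n1 / 4 - n2), 1)
  # monotone in power
  expect_gt(min_sample_size(0.5, 0.05, 0.95)$n_total,
            min_sample_size(0.5, 0.05, 0.8)$n_total)
  expect_error(min_sample_size(-1), "effect_size_d")
})

test_that("roc_points is internally consistent", {
  set.seed(71)
  y <- rep(c(0L, 1L), each = 15)
  s <- y + rnorm(30)
  rc <- roc_points(s, y)
  expect_equal(rc$auc, auc(s, y))
  expect_true(all(diff(rc$sensitivity) <= 1e-12)) # nonincreasing in threshold
  expect_equal(rc$n_cases, 15L)
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$specificity[length(rc$specificity)], 1)
})
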