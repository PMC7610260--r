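test_that("softmax outputs are normalized for any input through an untrained model", {
  arch <- sn_architecture(30, lc_layers = list(list(kernel = 5, stride = 2,
                                                    channels = 3)),
                          fc_layers = c(8))
  m <- build_model(arch, seed = 4)
  set.seed(1)
  X <- matrix(rnorm(7 * 30), 7, 30)
  p <- smfdx:::nn_forward(m, X)$probs
  expect_true(all(p > 0 & p < 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("locally connected parameter count matches the closed form", {
  # out_positions * (kernel + 1) * channels over one input channel,
  # verified against explicit enumeration of the constructed block
  cases <- list(c(W = 40, k = 5, s = 2, c = 3),
                c(W = 881, k = 9, s = 3, c = 8),
                c(W = 12, k = 3, s = 1, c = 2))
  for (cs in cases) {
    P <- floor((cs["W"] - cs["k"]) / cs["s"]) + 1
    L <- smfdx:::new_lc_layer(cs["W"], 1L, cs["k"], cs["s"], cs["c"])
    expect_equal(length(L$w) + length(L$b),
                 unname(P * (cs["k"] + 1) * cs["c"]))
    # enumeration: each output unit owns kernel weights + shares no others
    expect_equal(length(L$w), unname(P * cs["c"] * cs["k"]))
    expect_equal(Matrix::nnzero(L$S), length(L$w))
  }
})

test_that("unshared weights: distinct positions own distinct parameters", {
  L <- smfdx:::new_lc_layer(10L, 1L, 3L, 2L, 1L)
  L <- smfdx:::lc_set_weights(L, seq_along(L$w))
  S <- as.matrix(L$S)
  # position 1 reads inputs 1:3, position 2 reads 3:5; the shared input 3
  # feeds both but through different weights
  expect_equal(which(S[, 1] != 0), 1:3, ignore_attr = TRUE)
  expect_equal(which(S[, 2] != 0), 3:5, ignore_attr = TRUE)
  expect_false(S[3, 1] == S[3, 2])
})

test_that("kernels wider than their layer input are rejected", {
  expect_error(sn_architecture(20, lc_layers = list(
    list(kernel = 25, stride = 1, channels = 2))), "architecture error")
  expect_error(sn_architecture(30, lc_layers = list(
    list(kernel = 9, stride = 3, channels = 2),
    list(kernel = 9, stride = 3, channels = 2))), "architecture error")
})

test_that("training is deterministic and learns a separable toy", {
  set.seed(2)
  n <- 200
  X <- cbind(rnorm(n), rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 5
  arch <- sn_architecture(2, lc_layers = list(), fc_layers = c(8),
                          dropout_rate = 0.2, input_dropout = 0)
  cfg <- train_config(max_epochs = 30, early_stop_patience = 5,
                      early_stop_burn_in = 30, seed = 7)
  m1 <- train_classifier(X, y, arch = arch, config = cfg, transform = "none")
  m2 <- train_classifier(X, y, arch = arch, config = cfg, transform = "none")
  s1 <- predict_scores(m1, X)
  expect_identical(s1, predict_scores(m2, X))
  expect_gte(mean((s1 > 0.5) == (y == 1)), 0.95)
  expect_gte(auc(s1, y), 0.95)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # prediction is a pure function and equivariant under row permutation
  expect_identical(s1, predict_scores(m1, X))
  perm <- sample(n)
  expect_equal(predict_scores(m1, X[perm, ]), s1[perm])
})

test_that("history has one entry per completed epoch up to the cap", {
  set.seed(3)
  to <- toy_gaussian(30, 4, d = 1, seed = 3)
  cfg <- train_config(max_epochs = 12, holdout_fraction = 0, seed = 1)
  m <- train_classifier(to$X, to$y, arch = mlp_architecture(4), config = cfg,
                        transform = "none")
  expect_equal(nrow(m$history), 12L)
  expect_equal(m$history$epoch, 1:12)
  expect_named(m$history, c("epoch", "train_loss", "train_acc",
                            "monitor_loss", "monitor_acc"))
})

test_that("training rejects degenerate label and shape inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(train_classifier(X, rep(1L, 10)), "single class")
  expect_error(train_classifier(X, c(0L, 1L)), "shape error")
  expect_error(train_classifier(X, rep(c(0L, 1L), 5),
                                clinical = matrix(1, 3, 2)), "shape error")
})

test_that("multi-modal model widths are enforced at fit and predict time", {
  set.seed(4)
  to <- toy_gaussian(25, 6, d = 1, seed = 4)
  clin <- matrix(rnorm(50 * 2), 50, 2)
  arch <- sn_architecture(6, clinical_width = 2, lc_layers = list(),
                          fc_layers = c(6), input_dropout = 0)
  cfg <- train_config(max_epochs = 10, holdout_fraction = 0, seed = 2)
  m <- train_classifier(to$X, to$y, clinical = clin, arch = arch,
                        config = cfg, transform = "none")
  expect_error(predict_scores(m, to$X), "clinical block")
  expect_error(predict_scores(m, to$X, clin[, 1, drop = FALSE]), "shape error")
  s <- predict_scores(m, to$X, clin)
  expect_length(s, 50)
  # fingerprint-only model rejects a clinical block
  m0 <- train_classifier(to$X, to$y, arch = sn_architecture(6, lc_layers = list(),
                                                            fc_layers = c(6),
                                                            input_dropout = 0),
                         config = cfg, transform = "none")
  expect_error(predict_scores(m0, to$X, clin), "no clinical block")
  expect_error(build_csn(sn_architecture(6, lc_layers = list())), "clinical_width")
})

test_that("a label-leaking clinical column drives validation AUC to ~1", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(0L, 1L), n / 2)
  clin <- cbind(leak = y, noise = rnorm(n))
  tr <- 1:80
  va <- 81:n
  arch <- sn_architecture(10, clinical_width = 2, lc_layers = list(),
                          fc_layers = c(8), input_dropout = 0)
  m <- train_classifier(X[tr, ], y[tr], clinical = clin[tr, ], arch = arch,
                        config = train_config(max_epochs = 80,
                                              learning_rate = 5e-3,
                                              holdout_fraction = 0, seed = 3),
                        transform = "none")
  expect_gte(auc(predict_scores(m, X[va, ], clin[va, ]), y[va]), 0.99)
})

test_that("constant clinical columns leave the fusion model near the plain one", {
  # constant columns are zero after standardization, so the fusion model
  # differs from the plain one only through weight-initialization noise;
  # averaged over seeds the validation AUCs must coincide
  to <- toy_gaussian(130, 6, d = 0.55, seed = 6)
  tr <- c(1:100, 131:230)
  va <- setdiff(seq_len(260), tr)
  clin <- matrix(1, 260, 2)
  diffs <- sapply(1:10, function(s) {
    cfg <- train_config(max_epochs = 40, holdout_fraction = 0, seed = s)
    arch0 <- sn_architecture(6, lc_layers = list(), fc_layers = c(8),
                             input_dropout = 0)
    archc <- sn_architecture(6, clinical_width = 2, lc_layers = list(),
                             fc_layers = c(8), input_dropout = 0)
    m0 <- train_classifier(to$X[tr, ], to$y[tr], arch = arch0, config = cfg,
                           transform = "none")
    mc <- train_classifier(to$X[tr, ], to$y[tr], clinical = clin[tr, ],
                           arch = archc, config = cfg, transform = "none")
    auc(predict_scores(mc, to$X[va, ], clin[va, ]), to$y[va]) -
      auc(predict_scores(m0, to$X[va, ]), to$y[va])
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("linear scorer reproduces its defining weights", {
  w <- c(2, -1, 0.5)
  m <- linear_scorer(w, bias = 0.3)
  X <- matrix(rnorm(15), 5, 3)
  s <- predict_scores(m, X)
  expect_equal(s, plogis(drop(X %*% w) + 0.3))
})
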