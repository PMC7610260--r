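small_cfg <- function(n_bins = 40, ...) {
  cohort_config(n_controls = 30, n_cases = 30, n_bins = n_bins,
                planted_bins = data.frame(bin_index = c(5L, 17L),
                                          direction = c("up", "down"),
                                          effect_size = 4),
                sample_scale_log_sd = 0, missing_rate = 0, ...)
}

test_that("cohort generation is deterministic and structurally sound", {
  a <- generate_cohort(small_cfg(seed = 7))
  b <- generate_cohort(small_cfg(seed = 7))
  expect_identical(a$fingerprints, b$fingerprints)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$fingerprints >= 0))
  expect_equal(nrow(a$fingerprints), length(a$labels))
  expect_equal(nrow(a$clinical), length(a$labels))
  expect_setequal(unique(a$labels), c(0L, 1L))
  d <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$fingerprints, d$fingerprints))
})

test_that("configuration errors name the violated field", {
  expect_error(cohort_config(n_controls = 0), "n_controls")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(small_cfg(n_bins = 10), "planted_bins")
  expect_error(
    cohort_config(planted_bins = data.frame(bin_index = c(3L, 3L),
                                            direction = "up",
                                            effect_size = 2)),
    "planted_bins")
  expect_error(
    cohort_config(planted_bins = data.frame(bin_index = 3L, direction = "up",
                                            effect_size = 0)),
    "effect_size")
})

test_that("a strongly planted bin is a near-perfect single-feature classifier", {
  cfg <- cohort_config(n_controls = 100, n_cases = 100, n_bins = 30,
                       planted_bins = data.frame(bin_index = 11L,
                                                 direction = "up",
                                                 effect_size = 16),
                       sample_scale_log_sd = 0, missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  a <- pair_count_auc(co$fingerprints[, 11], co$labels)
  expect_gte(a, 0.95)
  expect_equal(auc(co$fingerprints[, 11], co$labels), a)
})

test_that("null configurations produce exchangeable classes", {
  # two-sample tests on a fixed bin reject at ~ the nominal rate
  rejections <- 0L
  n_sims <- 200L
  for (i in seq_len(n_sims)) {
    cfg <- cohort_config(n_controls = 15, n_cases = 15, n_bins = 3,
                         planted_bins = default_planted_bins(3, k = 0),
                         clinical_spec = data.frame(index_name = "a",
                                                    control_mean = 1,
                                                    case_mean = 1, sd = 1),
                         sample_scale_log_sd = 0, missing_rate = 0, seed = i)
    co <- generate_cohort(cfg)
    p <- t.test(log(co$fingerprints[, 2]) ~ co$labels)$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_sims, 0.01)
  expect_lt(rejections / n_sims, 0.12)
})

test_that("planted log fold change matches the configured effect size", {
  cfg <- cohort_config(seed = 13) # default 172/172, 20 planted bins @ 2-fold
  co <- generate_cohort(cfg)
  tr <- ground_truth(co)
  lfp <- log(co$fingerprints)
  for (r in seq_len(nrow(tr))) {
    j <- tr$bin_index[r]
    delta <- mean(lfp[co$labels == 1, j]) - mean(lfp[co$labels == 0, j])
    se <- sqrt(var(lfp[co$labels == 1, j]) / 172 + var(lfp[co$labels == 0, j]) / 172)
    want <- if (tr$direction[r] == "up") log(2) else -log(2)
    expect_lt(abs(delta - want), 3 * se)
  }
})

test_that("ground truth round-trips the planted configuration", {
  co <- generate_cohort(small_cfg(seed = 1))
  tr <- ground_truth(co)
  expect_equal(tr$bin_index, c(5L, 17L))
  expect_equal(tr$direction, c("up", "down"))
  co0 <- generate_cohort(cohort_config(n_controls = 10, n_cases = 10,
                                       n_bins = 8,
                                       planted_bins = default_planted_bins(8, k = 0),
                                       seed = 2))
  expect_equal(nrow(ground_truth(co0)), 0L)
  co20 <- generate_cohort(cohort_config(seed = 2))
  expect_equal(nrow(ground_truth(co20)), 20L)
})

test_that("stratified splitting reproduces the target cohort shape", {
  co <- generate_cohort(cohort_config(seed = 5))
  sp <- split_cohort(co, 0.2, seed = 9)
  expect_equal(length(sp$validation), 69L)
  expect_equal(length(sp$discovery), 275L)
  vt <- table(co$labels[sp$validation])
  expect_setequal(as.integer(vt), c(34L, 35L))
  dt <- table(co$labels[sp$discovery])
  expect_setequal(as.integer(dt), c(137L, 138L))
  # partition
  expect_length(intersect(sp$discovery, sp$validation), 0)
  expect_setequal(c(sp$discovery, sp$validation), seq_along(co$labels))
  # determinism
  sp2 <- split_cohort(co, 0.2, seed = 9)
  expect_identical(sp, sp2)
})

test_that("splitting preserves stratification on small balanced cohorts", {
  y <- rep(c(0L, 1L), each = 5)
  sp <- split_cohort(y, 0.5, seed = 4)
  expect_equal(length(sp$validation), 5L)
  expect_setequal(as.integer(table(y[sp$validation])), c(2L, 3L))
  expect_error(split_cohort(c(0L, 1L, 1L), 0.5), "2 members")
  expect_error(split_cohort(rep(1L, 10), 0.2), "both classes")
})

test_that("cohorts round-trip through the plain-text export", {
  co <- generate_cohort(small_cfg(seed = 6))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  m <- read_fingerprints(file.path(d, "fingerprints.tsv"))
  expect_equal(unname(m), unname(co$fingerprints), tolerance = 1e-8)
  lb <- read.csv(file.path(d, "labels.csv"))
  expect_equal(lb$label, co$labels)
  tr <- read.csv(file.path(d, "truth.csv"))
  expect_equal(tr$bin_index, ground_truth(co)$bin_index)
})
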