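#' Configuration for a synthetic case/control fingerprint cohort
#'
#' Describes a cohort of serum metabolic fingerprints with planted
#' discriminative structure. Baseline bin intensities are independent
#' log-normal; cases have the planted bins shifted multiplicatively (up or
#' down) by `effect_size`, i.e. additively by `log(effect_size)` on the log
#' scale. An optional per-sample log-normal scaling factor emulates total
#' ion current variation between acquisitions. Clinical indexes are drawn
#' normal per group with values deleted completely at random at
#' `missing_rate`.
#'
#' The defaults emulate a balanced screening cohort of 172 controls and
#' 172 cases on the standard 881-bin grid, with 20 planted bins at a 2-fold
#' effect (half up-, half down-regulated) and three clinical indexes
#' (gamma-glutamyl transferase in U/L, albumin in g/L, albumin/globulin
#' ratio) with modest group separation.
#'
#' @param n_controls,n_cases group sizes.
#' @param n_bins number of m/z bins.
#' @param mz_min,mz_max grid mass range in Da.
#' @param planted_bins data.frame with columns `bin_index` (1-based),
#'   `direction` (`"up"`/`"down"`) and `effect_size` (multiplicative fold
#'   > 0); may have zero rows.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of
#'   baseline bin intensity; `baseline_log_mean` may be a vector of length
#'   `n_bins`.
#' @param sample_scale_log_sd standard deviation of the per-sample
#'   log-normal scale factor (0 disables it).
#' @param clinical_spec data.frame with columns `index_name`,
#'   `control_mean`, `case_mean`, `sd`; may have zero rows.
#' @param missing_rate fraction of clinical values deleted at random.
#' @param seed integer seed; the single source of randomness.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_controls = 172, n_cases = 172, n_bins = 881,
                          mz_min = 100, mz_max = 1000,
                          planted_bins = default_planted_bins(n_bins),
                          baseline_log_mean = log(100), baseline_log_sd = 1,
                          sample_scale_log_sd = 0.3,
                          clinical_spec = default_clinical_spec(),
                          missing_rate = 0.05, seed = 1L) {
  n_controls <- check_count(n_controls, "n_controls")
  n_cases <- check_count(n_cases, "n_cases")
  n_bins <- check_count(n_bins, "n_bins")
  if (mz_min >= mz_max) stop_config("mz_min/mz_max", "must satisfy mz_min < mz_max")
  planted_bins <- validate_planted(planted_bins, n_bins)
  if (!is.numeric(baseline_log_mean) ||
      !(length(baseline_log_mean) %in% c(1L, n_bins))) {
    stop_config("baseline_log_mean", "must be scalar or of length n_bins")
  }
  if (baseline_log_sd < 0) stop_config("baseline_log_sd", "must be >= 0")
  if (sample_scale_log_sd < 0) stop_config("sample_scale_log_sd", "must be >= 0")
  clinical_spec <- validate_clinical_spec(clinical_spec)
  check_prob(missing_rate, "missing_rate")
  structure(
    list(n_controls = n_controls, n_cases = n_cases, n_bins = n_bins,
         mz_min = mz_min, mz_max = mz_max, planted_bins = planted_bins,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         sample_scale_log_sd = sample_scale_log_sd,
         clinical_spec = clinical_spec, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default planted feature panel: 20 bins at 2-fold effect
#'
#' Ten up- and ten down-regulated bins spread evenly across the grid.
#'
#' @param n_bins grid size.
#' @param k panel size.
#' @param effect_size multiplicative fold.
#' @return data.frame usable as `planted_bins` in [cohort_config()].
#' @export
default_planted_bins <- function(n_bins = 881, k = 20, effect_size = 2) {
  if (k == 0) {
    return(data.frame(bin_index = integer(), direction = character(),
                      effect_size = numeric()))
  }
  idx <- unique(pmax(1, pmin(n_bins, round(seq(n_bins * 0.05, n_bins * 0.95,
                                               length.out = k)))))
  data.frame(
    bin_index = as.integer(idx),
    direction = rep(c("up", "down"), length.out = length(idx)),
    effect_size = effect_size
  )
}

#' Default clinical index specification
#'
#' Three routinely collected serum indexes with realistic units and a
#' modest case shift: gamma-glutamyl transferase (U/L), albumin (g/L) and
#' the albumin/globulin ratio.
#'
#' @return data.frame usable as `clinical_spec` in [cohort_config()].
#' @export
default_clinical_spec <- function() {
  data.frame(
    index_name = c("ggt", "albumin", "ag_ratio"),
    control_mean = c(28, 45, 1.55),
    case_mean = c(36, 43.5, 1.45),
    sd = c(18, 4, 0.25)
  )
}

validate_planted <- function(pb, n_bins) {
  req <- c("bin_index", "direction", "effect_size")
  if (!is.data.frame(pb) || !all(req %in% names(pb))) {
    stop_config("planted_bins", "must be a data.frame with bin_index, direction, effect_size")
  }
  if (nrow(pb) == 0) return(pb)
  if (anyDuplicated(pb$bin_index)) stop_config("planted_bins", "bin indices must be unique")
  if (any(pb$bin_index < 1 | pb$bin_index > n_bins)) {
    stop_config("planted_bins", "bin indices must lie in 1..n_bins")
  }
  if (!all(pb$direction %in% c("up", "down"))) {
    stop_config("planted_bins", "direction must be 'up' or 'down'")
  }
  if (any(pb$effect_size <= 0)) stop_config("planted_bins", "effect_size must be > 0")
  pb
}

validate_clinical_spec <- function(cs) {
  req <- c("index_name", "control_mean", "case_mean", "sd")
  if (!is.data.frame(cs) || !all(req %in% names(cs))) {
    stop_config("clinical_spec", "must be a data.frame with index_name, control_mean, case_mean, sd")
  }
  if (nrow(cs) && any(cs$sd < 0)) stop_config("clinical_spec", "sd must be >= 0")
  if (anyDuplicated(cs$index_name)) stop_config("clinical_spec", "index names must be unique")
  cs
}

#' Generate a synthetic fingerprint cohort
#'
#' Deterministic given `cfg$seed`. Controls come first, then cases. On the
#' log-intensity scale each bin is `baseline_log_mean + sample_scale +
#' N(0, baseline_log_sd)`, and each planted bin in a case is additionally
#' shifted by `+/- log(effect_size)`. Non-planted bins are identically
#' distributed in both classes.
#'
#' @param cfg a [cohort_config()].
#' @return A `synthetic_cohort`: list with `fingerprints` (matrix, samples
#'   x bins, bin centers as column names), `clinical` (data.frame),
#'   `labels` (0 control / 1 case), `truth` (the planted panel) and `grid`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_controls + cfg$n_cases
  labels <- c(rep(0L, cfg$n_controls), rep(1L, cfg$n_cases))
  grid <- mz_grid(cfg$mz_min, cfg$mz_max, cfg$n_bins)

  logm <- matrix(stats::rnorm(n * cfg$n_bins, sd = cfg$baseline_log_sd),
                 nrow = n, ncol = cfg$n_bins)
  logm <- sweep(logm, 2, rep(cfg$baseline_log_mean, length.out = cfg$n_bins), "+")
  if (cfg$sample_scale_log_sd > 0) {
    logm <- logm + stats::rnorm(n, sd = cfg$sample_scale_log_sd)
  }
  if (nrow(cfg$planted_bins)) {
    shift <- ifelse(cfg$planted_bins$direction == "up", 1, -1) *
      log(cfg$planted_bins$effect_size)
    cases <- which(labels == 1L)
    logm[cases, cfg$planted_bins$bin_index] <-
      logm[cases, cfg$planted_bins$bin_index] +
      matrix(shift, nrow = length(cases), ncol = length(shift), byrow = TRUE)
  }
  fp <- exp(logm)
  rownames(fp) <- sprintf("S%04d", seq_len(n))
  colnames(fp) <- format(grid$centers, trim = TRUE)

  clinical <- as.data.frame(
    lapply(seq_len(nrow(cfg$clinical_spec)), function(j) {
      spec <- cfg$clinical_spec[j, ]
      mu <- ifelse(labels == 1L, spec$case_mean, spec$control_mean)
      x <- stats::rnorm(n, mean = mu, sd = spec$sd)
      if (cfg$missing_rate > 0) {
        x[stats::runif(n) < cfg$missing_rate] <- NA_real_
      }
      x
    })
  )
  names(clinical) <- cfg$clinical_spec$index_name
  if (ncol(clinical)) rownames(clinical) <- rownames(fp)

  structure(
    list(fingerprints = fp, clinical = clinical, labels = labels,
         truth = cfg$planted_bins[, c("bin_index", "direction")],
         grid = grid, config = cfg),
    class = "synthetic_cohort"
  )
}

#' Planted ground truth of a synthetic cohort
#'
#' Oracle for feature-recovery experiments: the planted (bin, direction)
#' panel exactly as configured.
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame with `bin_index` and `direction`.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

#' Stratified discovery/validation split
#'
#' Random split stratified by class label: each class contributes
#' `round(validation_fraction * n)` samples overall, allocated per class by
#' largest remainder so per-class counts differ from exact proportionality
#' by at most one. Deterministic given `seed`.
#'
#' @param labels binary label vector (or a `synthetic_cohort`).
#' @param validation_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return A `cohort_split`: list with integer index vectors
#'   `discovery` and `validation`.
#' @export
split_cohort <- function(labels, validation_fraction = 0.2, seed = 1L) {
  if (inherits(labels, "synthetic_cohort")) labels <- labels$labels
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    stop_config("validation_fraction", "must lie in (0, 1)")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("split requires both classes present", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("split requires at least 2 members per class", call. = FALSE)
  }
  n <- length(labels)
  n_val <- round(validation_fraction * n)
  n_val <- max(length(classes), min(n - length(classes), n_val))
  # largest-remainder allocation of n_val across classes
  cls_n <- as.numeric(table(factor(labels, levels = classes)))
  exact <- n_val * cls_n / n
  base <- floor(exact)
  rem <- n_val - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base <- pmax(1, pmin(cls_n - 1, base))
  set.seed(seed)
  validation <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    validation <- c(validation, sample(idx, base[k]))
  }
  validation <- sort(validation)
  structure(
    list(discovery = setdiff(seq_len(n), validation), validation = validation),
    class = "cohort_split"
  )
}

#' Write a synthetic cohort as plain-text files
#'
#' Writes `fingerprints.tsv` (tab-separated, bin-center header),
#' `clinical.csv`, `labels.csv` (`sample_id,label`) and `truth.csv`
#' (`bin_index,direction`) into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fingerprints(cohort$fingerprints, file.path(dir, "fingerprints.tsv"))
  utils::write.csv(
    data.frame(sample_id = rownames(cohort$fingerprints), cohort$clinical,
               check.names = FALSE),
    file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = rownames(cohort$fingerprints), label = cohort$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
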