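#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles every stage configuration. All randomness flows from the master
#' seed: each stage draws its own seed via [derive_seed()] so any stage can
#' be reproduced in isolation.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param validation_fraction held-out fraction for the
#'   discovery/validation split.
#' @param normalize apply TIC normalization to fingerprints before
#'   modelling.
#' @param train a [train_config()] (its seed is overridden per stage).
#' @param saliency_k feature-panel size.
#' @param ci_level confidence level for AUC intervals.
#' @param cv_folds folds for cross-validated procedures.
#' @param seed master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            validation_fraction = 0.2, normalize = TRUE,
                            train = train_config(), saliency_k = 20,
                            ci_level = 0.95, cv_folds = 10, seed = 1L) {
  if (is.null(cohort)) stop_config("cohort", "is required")
  stopifnot(inherits(cohort, "cohort_config"), inherits(train, "train_config"))
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    stop_config("validation_fraction", "must lie in (0, 1)")
  }
  saliency_k <- check_count(saliency_k, "saliency_k")
  if (saliency_k > cohort$n_bins) {
    stop_config("saliency_k", "must not exceed the number of bins")
  }
  structure(
    list(cohort = cohort, validation_fraction = validation_fraction,
         normalize = isTRUE(normalize), train = train,
         saliency_k = saliency_k, ci_level = ci_level,
         cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `cohort`
#' and `train` are nested mappings passed to [cohort_config()] and
#' [train_config()]. `cohort` is required. `planted_bins` and
#' `clinical_spec` may be given as lists of records.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cohort)) {
    stop_config("cohort", "is missing from the pipeline configuration")
  }
  co <- raw$cohort
  for (fld in c("planted_bins", "clinical_spec")) {
    if (!is.null(co[[fld]]) && !is.data.frame(co[[fld]])) {
      co[[fld]] <- do.call(rbind, lapply(co[[fld]], as.data.frame))
    }
  }
  cohort <- do.call(cohort_config, co)
  train <- if (is.null(raw$train)) train_config() else do.call(train_config, raw$train)
  args <- raw[setdiff(names(raw), c("cohort", "train"))]
  do.call(pipeline_config, c(list(cohort = cohort, train = train), args))
}

with_seed_cfg <- function(cfg, seed) {
  cfg$seed <- seed
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates, on synthetic data: cohort simulation, TIC normalization,
#' the stratified discovery/validation split, training of the fingerprint
#' network (SN), its clinical-fusion variant (CSN) and a clinical-only
#' network, the four classical baselines, the split evaluation report with
#' Youden thresholds fixed on discovery, the gradient-saliency feature
#' panel, and a panel-restricted refit. Rerunning with the same
#' configuration reproduces every output file bit-identically.
#'
#' @param config a [pipeline_config()] or a path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir output directory; created if needed. Files written:
#'   `report.csv` (Table-style rows: input data, algorithm, cohort, AUC,
#'   CI bounds, sensitivity, specificity), `roc_points.csv`, `panel.csv`,
#'   `saliency_grid.tsv`, `manifest.json`, plus the cohort files.
#' @return Invisibly, a list with the report, models, scores, panel and
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(
    simulate = derive_seed(config$seed, "simulate"),
    split = derive_seed(config$seed, "split"),
    sn = derive_seed(config$seed, "sn"),
    csn = derive_seed(config$seed, "csn"),
    clinical = derive_seed(config$seed, "clinical"),
    baselines = derive_seed(config$seed, "baselines"),
    panel = derive_seed(config$seed, "panel")
  )

  cohort <- generate_cohort(with_seed_cfg(config$cohort, seeds$simulate))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  X <- cohort$fingerprints
  if (config$normalize) X <- tic_normalize(X)
  y <- cohort$labels
  split <- split_cohort(y, config$validation_fraction, seed = seeds$split)
  di <- split$discovery
  vi <- split$validation

  clin_prep <- fit_clinical_prep(cohort$clinical[di, , drop = FALSE])
  clin_imp <- apply_clinical_prep(cohort$clinical, clin_prep)

  scores <- list()
  models <- list()

  # clinical-index-only network
  m <- train_classifier(clin_imp[di, , drop = FALSE], y[di],
                        arch = mlp_architecture(ncol(clin_imp)),
                        config = with_seed_cfg(config$train, seeds$clinical),
                        transform = "none")
  models$clinical_sn <- m
  scores$clinical_sn <- list(discovery = predict_scores(m, clin_imp[di, , drop = FALSE]),
                             validation = predict_scores(m, clin_imp[vi, , drop = FALSE]))

  # fingerprint network (SN)
  m <- train_classifier(X[di, , drop = FALSE], y[di],
                        config = with_seed_cfg(config$train, seeds$sn))
  models$sn <- m
  scores$sn <- list(discovery = predict_scores(m, X[di, , drop = FALSE]),
                    validation = predict_scores(m, X[vi, , drop = FALSE]))

  # classical baselines on fingerprints
  base_names <- c(lasso = "LASSO", random_forest = "RF", svm = "SVM",
                  opls_da = "OPLS-DA")
  for (nm in names(base_names)) {
    b <- run_baseline(nm, X[di, , drop = FALSE], y[di],
                      seed = derive_seed(seeds$baselines, nm))
    models[[nm]] <- b
    scores[[nm]] <- list(discovery = b$scores,
                         validation = predict(b, X[vi, , drop = FALSE]))
  }

  # clinical-fusion network (CSN)
  m <- train_classifier(X[di, , drop = FALSE], y[di],
                        clinical = cohort$clinical[di, , drop = FALSE],
                        config = with_seed_cfg(config$train, seeds$csn))
  models$csn <- m
  scores$csn <- list(
    discovery = predict_scores(m, X[di, , drop = FALSE],
                               cohort$clinical[di, , drop = FALSE]),
    validation = predict_scores(m, X[vi, , drop = FALSE],
                                cohort$clinical[vi, , drop = FALSE]))

  # gradient-saliency feature panel from the multi-modal network
  sal <- saliency_map(models$csn, X[di, , drop = FALSE],
                      cohort$clinical[di, , drop = FALSE])
  aggregate <- aggregate_saliency(sal$smf)
  panel <- select_panel(aggregate, k = config$saliency_k,
                        X = X[di, , drop = FALSE], labels = y[di],
                        bin_centers = cohort$grid$centers)
  refit <- refit_on_panel(panel, X, y, split,
                          config = with_seed_cfg(config$train, seeds$panel))
  models$panel_sn <- refit$model
  scores$panel_sn <- refit$scores

  row_specs <- list(
    clinical_sn = c("Clinical indexes", "SN"),
    sn = c("Serum metabolic fingerprints (SMFs)", "SN"),
    lasso = c("Serum metabolic fingerprints (SMFs)", "LASSO"),
    random_forest = c("Serum metabolic fingerprints (SMFs)", "RF"),
    svm = c("Serum metabolic fingerprints (SMFs)", "SVM"),
    opls_da = c("Serum metabolic fingerprints (SMFs)", "OPLS-DA"),
    csn = c("SMF based multi-modal data", "CSN"),
    panel_sn = c("Metabolite features", "SN")
  )
  report <- do.call(rbind, lapply(names(row_specs), function(key) {
    ev <- evaluate_split(scores[[key]]$discovery, y[di],
                         scores[[key]]$validation, y[vi],
                         level = config$ci_level)
    cbind(data.frame(input_data = row_specs[[key]][1],
                     algorithm = row_specs[[key]][2]), ev)
  }))

  roc_rows <- do.call(rbind, lapply(names(row_specs), function(key) {
    do.call(rbind, lapply(c("discovery", "validation"), function(coh) {
      lb <- if (coh == "discovery") y[di] else y[vi]
      rc <- roc_points(scores[[key]][[coh]], lb, level = config$ci_level)
      data.frame(model = key, cohort = coh, threshold = rc$thresholds,
                 sensitivity = rc$sensitivity, specificity = rc$specificity)
    }))
  }))

  layout <- make_layout(length(aggregate))
  grid2d <- to_grid(aggregate, layout)

  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  utils::write.csv(roc_rows, file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(panel), file.path(out_dir, "panel.csv"),
                   row.names = FALSE)
  utils::write.table(grid2d, file.path(out_dir, "saliency_grid.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = rownames(cohort$fingerprints)[c(di, vi)],
               cohort = rep(c("discovery", "validation"),
                            c(length(di), length(vi)))),
    file.path(out_dir, "split.csv"), row.names = FALSE)
  manifest <- list(
    package = "smfdx",
    master_seed = config$seed,
    stage_seeds = seeds,
    n_samples = length(y),
    n_bins = ncol(X),
    normalize = config$normalize,
    validation_fraction = config$validation_fraction,
    saliency_k = config$saliency_k,
    files = c("cohort/fingerprints.tsv", "cohort/clinical.csv",
              "cohort/labels.csv", "cohort/truth.csv", "split.csv",
              "report.csv", "roc_points.csv", "panel.csv",
              "saliency_grid.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(report = report, models = models, scores = scores,
                 panel = panel, split = split, cohort = cohort,
                 aggregate_saliency = aggregate, out_dir = out_dir))
}
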