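#' Square 2D layout of a fingerprint
#'
#' Fingerprints live on a 1D m/z grid but can be viewed as structured data
#' points on a 2D grid (like image pixels) for saliency visualization.
#' The layout is the smallest square grid (`rows = cols = ceiling(sqrt(
#' n_bins))`) with bins placed row-major; remaining cells are padding,
#' carry zero, and are excluded from any aggregation. The layout affects
#' only visualization — saliency is computed on the network's own inputs.
#'
#' @param n_bins number of fingerprint bins.
#' @return A `grid_layout`: list with `rows`, `cols`, `n_bins`, `n_padded`,
#'   and `mapping` (data.frame: `bin_index`, `row`, `col`).
#' @export
make_layout <- function(n_bins) {
  n_bins <- check_count(n_bins, "n_bins")
  side <- ceiling(sqrt(n_bins))
  idx <- seq_len(n_bins)
  structure(
    list(rows = side, cols = side, n_bins = n_bins,
         n_padded = side * side - n_bins,
         mapping = data.frame(bin_index = idx,
                              row = ((idx - 1L) %/% side) + 1L,
                              col = ((idx - 1L) %% side) + 1L)),
    class = "grid_layout"
  )
}

#' Convert a fingerprint to / from its 2D layout
#'
#' `to_grid` fills a rows x cols matrix row-major with the fingerprint,
#' padding trailing cells with zero; `from_grid` inverts it exactly on the
#' non-padded cells.
#'
#' @param v fingerprint vector of length `layout$n_bins`.
#' @param layout a [make_layout()].
#' @return `to_grid`: matrix; `from_grid`: vector.
#' @export
to_grid <- function(v, layout) {
  stopifnot(inherits(layout, "grid_layout"), length(v) == layout$n_bins)
  matrix(c(v, numeric(layout$n_padded)), layout$rows, layout$cols,
         byrow = TRUE)
}

#' @rdname to_grid
#' @param m matrix produced by `to_grid`.
#' @export
from_grid <- function(m, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  as.vector(t(m))[seq_len(layout$n_bins)]
}

#' Gradient saliency maps of a trained classifier
#'
#' For each sample, the saliency of an input bin is the absolute gradient
#' of the case-class pre-softmax score with respect to that bin, evaluated
#' at the sample with dropout disabled — the classical input-gradient
#' saliency map. Gradients are taken with respect to the network's own
#' standardized inputs (after the model's stored transform and per-bin
#' z-scoring), so saliencies are comparable across bins regardless of raw
#' intensity scale. For multi-modal models the clinical inputs' gradients
#' are computed but reported separately from the fingerprint map.
#'
#' @param model a trained `smf_classifier`.
#' @param X fingerprint matrix, samples x bins.
#' @param clinical clinical table (multi-modal models only).
#' @return List with `smf` (samples x bins nonnegative matrix) and
#'   `clinical` (samples x clinical_width matrix or NULL).
#' @export
saliency_map <- function(model, X, clinical = NULL) {
  stopifnot(inherits(model, "smf_classifier"))
  if (!isTRUE(model$trained)) {
    stop("saliency requires a trained model", call. = FALSE)
  }
  X <- as.matrix(X)
  if (ncol(X) != model$arch$input_width) {
    stop("shape error: input width does not match architecture", call. = FALSE)
  }
  cw <- model$arch$clinical_width
  if (cw > 0 && is.null(clinical)) {
    stop("shape error: this model requires a clinical block", call. = FALSE)
  }
  Xt <- apply_transform(X, model$transform %||% "none")
  Xs <- if (is.null(model$scaler)) Xt else apply_scaler(Xt, model$scaler)
  Cs <- NULL
  if (cw > 0) {
    Cs <- if (is.null(model$clin_prep)) as.matrix(clinical) else
      apply_clinical_prep(clinical, model$clin_prep)
  }
  fw <- nn_forward(model, Xs, Cs, training = FALSE, keep = TRUE)
  # d(case logit)/d(input); rows are independent samples, so one backward
  # pass with unit seeds on the case column gives every per-sample gradient
  dlogits <- matrix(c(0, 1), nrow(X), 2, byrow = TRUE)
  bw <- nn_backward(model, fw$cache, dlogits)
  smf <- abs(bw$d_input)
  clin_map <- if (cw > 0 && !is.null(bw$d_clinical)) abs(bw$d_clinical)
  dimnames(smf) <- dimnames(X)
  list(smf = smf, clinical = clin_map)
}

#' Aggregate per-sample saliency maps
#'
#' Arithmetic mean per bin over a sample set (by default all discovery
#' samples, both classes).
#'
#' @param maps samples x bins nonnegative matrix (e.g. `$smf` from
#'   [saliency_map()]).
#' @return Per-bin mean saliency vector.
#' @export
aggregate_saliency <- function(maps) {
  maps <- as.matrix(maps)
  if (nrow(maps) == 0L) stop("cannot aggregate an empty set of maps", call. = FALSE)
  colMeans(maps)
}

#' Select the top-k metabolite feature panel
#'
#' Ranks bins by aggregate saliency (ties broken toward the lower bin
#' index, deterministically), keeps the top k, and calls the regulation
#' direction of each selected bin from the discovery intensities: `up` if
#' the case mean exceeds the control mean, else `down`, with the
#' case/control mean ratio recorded as the fold change.
#'
#' @param aggregate per-bin aggregate saliency, from
#'   [aggregate_saliency()].
#' @param k panel size.
#' @param X discovery fingerprint matrix (used for direction calls).
#' @param labels discovery labels.
#' @param bin_centers optional m/z bin centers for annotation.
#' @return A `feature_panel` data.frame: `bin_index`, `bin_center_mz`,
#'   `score`, `direction`, `fold_change`, ordered by descending score.
#' @export
select_panel <- function(aggregate, k = 20, X, labels, bin_centers = NULL) {
  n_bins <- length(aggregate)
  if (k > n_bins) stop("k exceeds the number of bins", call. = FALSE)
  X <- as.matrix(X)
  stopifnot(ncol(X) == n_bins)
  labels <- as.integer(labels)
  ord <- order(-aggregate, seq_len(n_bins)) # ties -> lower bin index first
  top <- ord[seq_len(k)]
  mu_case <- colMeans(X[labels == 1L, top, drop = FALSE])
  mu_ctrl <- colMeans(X[labels == 0L, top, drop = FALSE])
  fold <- mu_case / mu_ctrl
  panel <- data.frame(
    bin_index = top,
    bin_center_mz = if (is.null(bin_centers)) NA_real_ else bin_centers[top],
    score = aggregate[top],
    direction = ifelse(mu_case > mu_ctrl, "up", "down"),
    fold_change = fold
  )
  class(panel) <- c("feature_panel", "data.frame")
  panel
}

#' Retrain the classifier on a selected feature panel
#'
#' Fits a fresh fingerprint classifier restricted to the panel bins on the
#' discovery cohort and evaluates it with the standard split harness,
#' measuring how much discriminative signal the panel retains.
#'
#' @param panel a `feature_panel`.
#' @param X full fingerprint matrix.
#' @param labels labels aligned to `X`.
#' @param split a `cohort_split`.
#' @param config a [train_config()].
#' @return List with `report` (the [evaluate_split()] rows), `model`, and
#'   `scores` (named list with discovery/validation score vectors).
#' @export
refit_on_panel <- function(panel, X, labels, split, config = train_config()) {
  stopifnot(inherits(panel, "feature_panel"), inherits(split, "cohort_split"))
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  X <- as.matrix(X)[, panel$bin_index, drop = FALSE]
  di <- split$discovery
  vi <- split$validation
  model <- train_classifier(X[di, , drop = FALSE], labels[di], config = config)
  sc_d <- predict_scores(model, X[di, , drop = FALSE])
  sc_v <- predict_scores(model, X[vi, , drop = FALSE])
  list(report = evaluate_split(sc_d, labels[di], sc_v, labels[vi]),
       model = model,
       scores = list(discovery = sc_d, validation = sc_v))
}
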