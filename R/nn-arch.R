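#' Architecture of the fingerprint classifier
#'
#' The classifier stacks (i) locally connected 1D blocks — convolution-like
#' layers whose filter weights are NOT shared across positions, so each
#' spectral window learns its own weights — for feature extraction, (ii) a
#' nonlinear feature-interaction stage of fully connected rectified layers
#' with dropout, and (iii) a linear 2-unit softmax classification layer.
#' With `clinical_width > 0` the clinical index vector is concatenated with
#' the flattened locally connected output at the input of feature-
#' interaction layer `fusion_point`, giving the multi-modal variant in
#' which both modalities influence all downstream layers.
#'
#' Defaults (four locally connected blocks, kernels of width 9 at stride 3
#' with 8, 8, 16, 16 channels; interaction layers of 64 and 16 units with
#' dropout 0.3, input dropout 0.5) are package choices: the classifier family fixes the layer
#' types, not these sizes, and all are configurable. For narrow inputs
#' (fewer than 60 bins, e.g. a selected feature panel) the default kernels
#' shrink to width 3 at stride 1 so four blocks still fit.
#'
#' @param input_width number of fingerprint bins.
#' @param clinical_width number of clinical index columns (0 = fingerprint
#'   only).
#' @param lc_layers list of locally connected blocks, each a list with
#'   `kernel`, `stride`, `channels`; may be empty (giving a plain
#'   multi-layer perceptron, used e.g. for clinical-only models).
#' @param fc_layers integer vector of feature-interaction layer widths;
#'   may be empty (direct linear softmax on the extracted features).
#' @param dropout_rate dropout fraction in `[0, 1)` applied after each
#'   feature-interaction layer during training.
#' @param input_dropout dropout fraction applied to the standardized input
#'   bins during training; randomly silencing spectral bins forces the
#'   extractor to learn redundant evidence instead of memorizing
#'   individual noise bins.
#' @param fusion_point index of the feature-interaction layer whose input
#'   receives the clinical vector (ignored when `clinical_width == 0`).
#'   Defaults to the last interaction layer: a handful of clinical columns
#'   concatenated onto the wide flattened spectral block would be diluted,
#'   while at the narrow final layer the two modalities meet at comparable
#'   dimensionality.
#' @param n_classes number of classes (binary only).
#' @return An `architecture_spec` object; `$widths` records the spatial
#'   width entering each locally connected block and `$flat_width` the
#'   flattened feature width.
#' @export
sn_architecture <- function(input_width, clinical_width = 0,
                            lc_layers = default_lc_layers(input_width),
                            fc_layers = c(64, 16),
                            dropout_rate = 0.3, input_dropout = 0.5,
                            fusion_point = NULL, n_classes = 2) {
  input_width <- check_count(input_width, "input_width")
  clinical_width <- check_count(clinical_width, "clinical_width", min = 0L)
  check_prob(dropout_rate, "dropout_rate")
  check_prob(input_dropout, "input_dropout")
  if (n_classes != 2L) stop_config("n_classes", "must be 2 (binary classifier)")
  if (!is.numeric(fc_layers)) stop_config("fc_layers", "must be an integer vector")
  fc_layers <- as.integer(fc_layers)
  if (length(fc_layers) && any(fc_layers < 1L)) {
    stop_config("fc_layers", "layer widths must be >= 1")
  }
  max_fuse <- max(1L, length(fc_layers))
  if (is.null(fusion_point)) fusion_point <- max_fuse
  if (clinical_width > 0 && !(fusion_point >= 1 && fusion_point <= max_fuse)) {
    stop_config("fusion_point", sprintf("must lie in 1..%d", max_fuse))
  }
  widths <- integer(0)
  w <- input_width
  ch <- 1L
  for (i in seq_along(lc_layers)) {
    blk <- lc_layers[[i]]
    if (!all(c("kernel", "stride", "channels") %in% names(blk))) {
      stop_config("lc_layers", "each block needs kernel, stride, channels")
    }
    if (blk$kernel > w) {
      stop(sprintf(
        "architecture error: locally connected block %d has kernel %d wider than its input width %d",
        i, blk$kernel, w), call. = FALSE)
    }
    if (blk$stride < 1 || blk$channels < 1) {
      stop_config("lc_layers", "stride and channels must be >= 1")
    }
    widths <- c(widths, w)
    w <- (w - blk$kernel) %/% blk$stride + 1L
    ch <- as.integer(blk$channels)
  }
  structure(
    list(input_width = input_width, clinical_width = clinical_width,
         lc_layers = lc_layers, fc_layers = fc_layers,
         dropout_rate = dropout_rate, input_dropout = input_dropout,
         fusion_point = as.integer(fusion_point),
         n_classes = 2L, widths = widths, flat_width = as.integer(w * ch)),
    class = "architecture_spec"
  )
}

#' Default locally connected stack for a given input width
#'
#' Four blocks; kernel 9 / stride 3 for wide fingerprints, kernel 3 /
#' stride 1 for narrow ones, with 8, 8, 16, 16 channels.
#'
#' @param input_width number of input bins.
#' @return List of block specifications for [sn_architecture()].
#' @export
default_lc_layers <- function(input_width) {
  blocks <- list()
  w <- input_width
  for (ch in c(8L, 8L, 16L, 16L)) {
    if (w >= 60) {
      k <- 9L; s <- 3L
    } else if (w >= 12) {
      k <- 3L; s <- 1L
    } else if (w >= 5) {
      k <- 2L; s <- 1L
    } else {
      break # too narrow for further local blocks
    }
    blocks[[length(blocks) + 1L]] <- list(kernel = k, stride = s, channels = ch)
    w <- (w - k) %/% s + 1L
  }
  blocks
}

#' Architecture for clinical-index-only models
#'
#' A plain multi-layer perceptron (no locally connected blocks): clinical
#' index vectors are short and unordered, so spatially local feature
#' extraction does not apply.
#'
#' @param input_width number of clinical columns.
#' @param fc_layers interaction layer widths.
#' @param dropout_rate dropout fraction.
#' @return An `architecture_spec`.
#' @export
mlp_architecture <- function(input_width, fc_layers = c(16, 8),
                             dropout_rate = 0.3) {
  sn_architecture(input_width, clinical_width = 0, lc_layers = list(),
                  fc_layers = fc_layers, dropout_rate = dropout_rate)
}
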