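#' Training configuration for the fingerprint classifier
#'
#' Training minimizes cross-entropy by mini-batch adaptive-moment gradient
#' descent (Adam). A stratified fraction of the training samples is held
#' out internally to monitor cross-entropy for early stopping: training
#' runs to `max_epochs` (default 80) or until the monitored loss has not
#' improved for `early_stop_patience` epochs, whichever comes first, and
#' the best-monitored weights are restored.
#'
#' @param max_epochs maximum number of passes through the data.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to every weight gradient
#'   (biases excluded); counters memorization in the heavily
#'   overparameterized small-n / large-p regime.
#' @param early_stop_patience epochs without improvement before stopping;
#'   must not exceed `max_epochs`.
#' @param early_stop_burn_in epochs trained before the early-stopping
#'   monitor may halt training; small monitor sets make the early loss
#'   curve noisy, so stopping is only armed once the fit has settled (best
#'   weights are still tracked from epoch 1).
#' @param holdout_fraction stratified fraction of training data used as the
#'   early-stopping monitor. 0 (the default) disables early stopping and
#'   trains to the epoch cap on all samples: at a few hundred training
#'   samples, giving up 10% of them to a monitor costs more accuracy than
#'   stopping earlier recovers, and with the regularized defaults the fit
#'   does not degrade before the cap.
#' @param lr_decay_epoch epoch after which the learning rate is multiplied
#'   by `lr_decay_factor` (a step schedule); the default factor of 1 keeps
#'   the rate constant.
#' @param lr_decay_factor multiplicative learning-rate drop in (0, 1].
#' @param min_delta smallest loss decrease counted as an improvement.
#' @param seed integer seed governing weight initialization, batch order,
#'   dropout and the monitor split.
#' @return A `train_config` object.
#' @export
train_config <- function(max_epochs = 80, batch_size = 32,
                         learning_rate = 2e-3, weight_decay = 1e-3,
                         early_stop_patience = 10, early_stop_burn_in = 40,
                         holdout_fraction = 0, min_delta = 1e-4,
                         lr_decay_epoch = 60, lr_decay_factor = 1,
                         seed = 1L) {
  max_epochs <- check_count(max_epochs, "max_epochs")
  batch_size <- check_count(batch_size, "batch_size")
  if (learning_rate <= 0) stop_config("learning_rate", "must be > 0")
  if (weight_decay < 0) stop_config("weight_decay", "must be >= 0")
  early_stop_patience <- check_count(early_stop_patience, "early_stop_patience", min = 0L)
  if (early_stop_patience > max_epochs) {
    stop_config("early_stop_patience", "must not exceed max_epochs")
  }
  early_stop_burn_in <- check_count(early_stop_burn_in, "early_stop_burn_in", min = 0L)
  check_prob(holdout_fraction, "holdout_fraction")
  lr_decay_epoch <- check_count(lr_decay_epoch, "lr_decay_epoch")
  if (!(lr_decay_factor > 0 && lr_decay_factor <= 1)) {
    stop_config("lr_decay_factor", "must lie in (0, 1]")
  }
  structure(
    list(max_epochs = max_epochs, batch_size = batch_size,
         learning_rate = learning_rate, weight_decay = weight_decay,
         early_stop_patience = early_stop_patience,
         early_stop_burn_in = early_stop_burn_in,
         holdout_fraction = holdout_fraction, min_delta = min_delta,
         lr_decay_epoch = lr_decay_epoch, lr_decay_factor = lr_decay_factor,
         loss = "cross_entropy", seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an untrained classifier from an architecture
#'
#' Initializes all weights (He-scaled normal draws, zero biases) under the
#' given seed. The returned model already makes predictions — softmax
#' probabilities summing to one — but carries no fitted information until
#' [train_classifier()] is run.
#'
#' @param arch an [sn_architecture()].
#' @param seed integer seed for weight initialization.
#' @return An `smf_classifier` object.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  model <- build_model_shell(arch, seed)
  set.seed(seed)
  init_model_params(model)
}

#' Build the multi-modal (clinical-fusion) variant
#'
#' Identical to [build_model()] but insists that the architecture declares
#' a clinical block, so the clinical index vector is concatenated into the
#' fully connected stage at the configured fusion point.
#'
#' @param arch an [sn_architecture()] with `clinical_width >= 1`.
#' @param seed integer seed.
#' @return An `smf_classifier`.
#' @export
build_csn <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  if (arch$clinical_width < 1) {
    stop("multi-modal model requires clinical_width >= 1; use build_model() for fingerprint-only",
         call. = FALSE)
  }
  build_model(arch, seed)
}

#' Total number of trainable parameters
#'
#' @param model an `smf_classifier`.
#' @return Integer parameter count (weights plus biases).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "smf_classifier"))
  n <- length(model$out$W) + length(model$out$b)
  for (L in model$lc) n <- n + length(L$w) + length(L$b)
  for (L in model$fc) n <- n + length(L$W) + length(L$b)
  n
}

apply_transform <- function(X, transform) {
  if (identical(transform, "log")) {
    if (any(X < 0)) {
      stop("log transform requires nonnegative intensities; use transform = 'none'",
           call. = FALSE)
    }
    return(log(X + 1e-12))
  }
  X
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# Fit median imputation + z-scaling on the discovery clinical table.
fit_clinical_prep <- function(clin) {
  clin <- as.matrix(clin)
  med <- apply(clin, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(clin))) clin[is.na(clin[, j]), j] <- med[j]
  sc <- fit_scaler(clin)
  list(medians = med, scaler = sc)
}

apply_clinical_prep <- function(clin, prep) {
  clin <- as.matrix(clin)
  for (j in seq_len(ncol(clin))) clin[is.na(clin[, j]), j] <- prep$medians[j]
  apply_scaler(clin, prep$scaler)
}

#' Train the fingerprint classifier
#'
#' Fits an `smf_classifier` on a fingerprint matrix (and, for the
#' multi-modal variant, an aligned clinical table) by mini-batch Adam with
#' dropout and early stopping. Fingerprint bins are z-scored with training
#' means/sds; clinical columns are median-imputed and z-scored with
#' training statistics; both transformations are stored in the model and
#' re-applied at prediction time. Identical seed and inputs yield identical
#' fitted weights.
#'
#' @param X numeric matrix, samples x bins.
#' @param y binary labels (0 = control, 1 = case).
#' @param clinical optional data.frame/matrix of clinical indexes aligned
#'   to the rows of `X`; required iff the architecture has
#'   `clinical_width > 0`.
#' @param arch an [sn_architecture()]; by default derived from the data
#'   dimensions.
#' @param config a [train_config()].
#' @param transform input transform applied before per-bin z-scoring:
#'   `"log"` (default; requires nonnegative inputs) or `"none"` (use for
#'   inputs that are not raw intensities, e.g. already-scaled clinical
#'   blocks or signed features).
#' @return The fitted `smf_classifier`, with `$history` holding one row per
#'   completed epoch (training and monitor loss/accuracy).
#' @export
train_classifier <- function(X, y, clinical = NULL, arch = NULL,
                             config = train_config(),
                             transform = c("log", "none")) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("shape error: length(y) != nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training error: labels contain a single class", call. = FALSE)
  }
  if (!is.null(clinical) && ncol(as.matrix(clinical)) == 0) clinical <- NULL
  if (!is.null(clinical) && nrow(as.matrix(clinical)) != nrow(X)) {
    stop("shape error: clinical rows do not align with X", call. = FALSE)
  }
  cw <- if (is.null(clinical)) 0L else ncol(as.matrix(clinical))
  if (is.null(arch)) arch <- sn_architecture(ncol(X), clinical_width = cw)
  if (arch$input_width != ncol(X)) {
    stop("shape error: ncol(X) does not match architecture input_width", call. = FALSE)
  }
  if (arch$clinical_width != cw) {
    stop("shape error: clinical width does not match architecture clinical_width",
         call. = FALSE)
  }

  set.seed(config$seed)
  model <- init_model_params(build_model_shell(arch, config$seed))
  model$transform <- transform
  Xt <- apply_transform(X, transform)
  model$scaler <- fit_scaler(Xt)
  Xs <- apply_scaler(Xt, model$scaler)
  Cs <- NULL
  if (cw > 0) {
    model$clin_prep <- fit_clinical_prep(clinical)
    Cs <- apply_clinical_prep(clinical, model$clin_prep)
  }

  n <- nrow(Xs)
  monitor_idx <- integer(0)
  if (config$holdout_fraction > 0) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      k <- max(1L, floor(config$holdout_fraction * length(idx)))
      if (k < length(idx)) monitor_idx <- c(monitor_idx, sample(idx, k))
    }
  }
  fit_idx <- setdiff(seq_len(n), monitor_idx)
  if (length(unique(y[fit_idx])) < 2L) {
    fit_idx <- seq_len(n)
    monitor_idx <- integer(0)
  }
  use_monitor <- length(monitor_idx) > 0 && config$early_stop_patience > 0

  state <- adam_init(model)
  best_loss <- Inf
  best_snap <- NULL
  wait <- 0L
  hist <- vector("list", config$max_epochs)
  Y1 <- y + 1L

  lr <- config$learning_rate
  for (epoch in seq_len(config$max_epochs)) {
    if (epoch == config$lr_decay_epoch + 1L) lr <- lr * config$lr_decay_factor
    ord <- sample(fit_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    loss_sum <- 0
    acc_sum <- 0
    for (s in starts) {
      b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      fw <- nn_forward(model, Xs[b, , drop = FALSE],
                       if (cw > 0) Cs[b, , drop = FALSE],
                       training = TRUE, keep = TRUE)
      Ymat <- matrix(0, length(b), 2L)
      Ymat[cbind(seq_along(b), Y1[b])] <- 1
      dlogits <- (fw$probs - Ymat) / length(b)
      bw <- nn_backward(model, fw$cache, dlogits)
      if (config$weight_decay > 0) {
        bw$grads <- add_weight_decay(bw$grads, model, config$weight_decay)
      }
      upd <- adam_step(model, bw$grads, state, lr)
      model <- upd$model
      state <- upd$state
      loss_sum <- loss_sum + cross_entropy(fw$probs, y[b]) * length(b)
      acc_sum <- acc_sum + sum((fw$probs[, 2] > 0.5) == (y[b] == 1L))
    }
    # running training metrics over the epoch's mini-batches (with dropout
    # active), the usual convention; avoids a second full forward pass
    tr_loss <- loss_sum / length(ord)
    tr_acc <- acc_sum / length(ord)
    if (use_monitor) {
      mo <- nn_forward(model, Xs[monitor_idx, , drop = FALSE],
                       if (cw > 0) Cs[monitor_idx, , drop = FALSE])
      mo_loss <- cross_entropy(mo$probs, y[monitor_idx])
      mo_acc <- mean((mo$probs[, 2] > 0.5) == (y[monitor_idx] == 1L))
    } else {
      mo_loss <- tr_loss
      mo_acc <- tr_acc
    }
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
                       monitor_loss = mo_loss, monitor_acc = mo_acc)
    if (mo_loss < best_loss - config$min_delta) {
      best_loss <- mo_loss
      # snapshots only once the fit has settled; the early monitor curve is
      # too noisy on small holdouts to pick weights from
      if (epoch > config$early_stop_burn_in) best_snap <- snapshot_params(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (use_monitor && epoch > config$early_stop_burn_in &&
          wait >= config$early_stop_patience) break
    }
  }
  if (!is.null(best_snap)) model <- restore_params(model, best_snap)
  model$history <- as.data.frame(rbind_list(hist[!vapply(hist, is.null, logical(1))]))
  model$trained <- TRUE
  model$config <- config
  model$seed <- config$seed
  model
}

# build_model without touching the RNG (train_classifier seeds once itself)
build_model_shell <- function(arch, seed) {
  lc <- list()
  w <- arch$input_width
  ch <- 1L
  for (blk in arch$lc_layers) {
    L <- new_lc_layer(w, ch, as.integer(blk$kernel), as.integer(blk$stride),
                      as.integer(blk$channels))
    lc[[length(lc) + 1L]] <- L
    w <- L$P
    ch <- L$out_ch
  }
  fc <- list()
  fan <- w * ch
  for (i in seq_along(arch$fc_layers)) {
    if (arch$clinical_width > 0 && i == arch$fusion_point) {
      fan <- fan + arch$clinical_width
    }
    fc[[i]] <- new_dense_layer(fan, arch$fc_layers[i])
    fan <- arch$fc_layers[i]
  }
  if (arch$clinical_width > 0 && length(arch$fc_layers) == 0) {
    fan <- fan + arch$clinical_width
  }
  out <- new_dense_layer(fan, arch$n_classes, activation = "linear")
  structure(
    list(arch = arch, lc = lc, fc = fc, out = out, scaler = NULL,
         clin_prep = NULL, history = NULL, trained = FALSE,
         seed = as.integer(seed)),
    class = "smf_classifier"
  )
}

#' Case scores from a classifier
#'
#' Softmax probability of the case class per sample; dropout is inactive,
#' so prediction is a pure function of the inputs and weights.
#'
#' @param model an `smf_classifier`.
#' @param X fingerprint matrix, samples x bins.
#' @param clinical clinical table aligned to `X` (multi-modal models only).
#' @return Numeric vector of case probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, X, clinical = NULL) {
  stopifnot(inherits(model, "smf_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != model$arch$input_width) {
    stop("shape error: input width does not match architecture", call. = FALSE)
  }
  cw <- model$arch$clinical_width
  if (cw > 0 && is.null(clinical)) {
    stop("shape error: this model requires a clinical block of width ", cw,
         call. = FALSE)
  }
  if (cw == 0 && !is.null(clinical)) {
    stop("shape error: this model takes no clinical block", call. = FALSE)
  }
  Xt <- apply_transform(X, model$transform %||% "none")
  Xs <- if (is.null(model$scaler)) Xt else apply_scaler(Xt, model$scaler)
  Cs <- NULL
  if (cw > 0) {
    clinical <- as.matrix(clinical)
    if (ncol(clinical) != cw || nrow(clinical) != nrow(X)) {
      stop("shape error: clinical block does not match architecture", call. = FALSE)
    }
    Cs <- if (is.null(model$clin_prep)) clinical else
      apply_clinical_prep(clinical, model$clin_prep)
  }
  nn_forward(model, Xs, Cs)$probs[, 2]
}

#' @export
print.smf_classifier <- function(x, ...) {
  cat(sprintf("<smf_classifier> %s, input %d bins%s, %d parameters, %s\n",
              if (length(x$lc)) sprintf("%d locally connected blocks", length(x$lc))
              else "multi-layer perceptron",
              x$arch$input_width,
              if (x$arch$clinical_width > 0)
                sprintf(" + %d clinical indexes", x$arch$clinical_width) else "",
              n_parameters(x),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' A fixed linear scorer as a degenerate classifier
#'
#' Builds an `smf_classifier` whose case logit is exactly `w . x + bias`
#' (control logit 0, identity input scaling, no hidden layers). Useful as
#' an analytically tractable model: its saliency map is `|w|` for every
#' sample.
#'
#' @param w weight vector.
#' @param bias intercept.
#' @return A trained-state `smf_classifier`.
#' @export
linear_scorer <- function(w, bias = 0) {
  arch <- sn_architecture(length(w), lc_layers = list(), fc_layers = integer(0),
                          dropout_rate = 0)
  model <- build_model_shell(arch, seed = 0L)
  model$out$W <- cbind(0, as.numeric(w))
  model$out$b <- c(0, bias)
  model$scaler <- list(mu = rep(0, length(w)), sd = rep(1, length(w)))
  model$transform <- "none"
  model$trained <- TRUE
  model
}
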