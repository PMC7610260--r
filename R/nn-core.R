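# Internal engine of the locally connected classifier: layer construction,
# forward pass, backpropagation. Tensors are laid out flat per sample with
# channel-fastest indexing: unit (position w, channel c) sits at column
# (w - 1) * C + c. A locally connected layer is a linear map with a banded
# sparsity pattern and position-specific weights, implemented as one sparse
# matrix multiply per layer; weight gradients are accumulated per spatial
# position so only the pattern's nonzeros are ever formed.

# Build one locally connected layer.
# in_width spatial positions x in_ch channels -> P positions x out_ch channels
new_lc_layer <- function(in_width, in_ch, kernel, stride, out_ch) {
  in_width <- as.integer(in_width); in_ch <- as.integer(in_ch)
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  out_ch <- as.integer(out_ch)
  P <- (in_width - kernel) %/% stride + 1L
  kc <- kernel * in_ch
  # window row indices per output position (ascending within each column)
  win <- vapply(seq_len(P), function(p) {
    w0 <- (p - 1L) * stride
    rep((w0 + seq_len(kernel) - 1L) * in_ch, each = in_ch) + rep(seq_len(in_ch), kernel)
  }, integer(kc))
  win <- matrix(win, nrow = kc, ncol = P)
  i_all <- as.vector(win[, rep(seq_len(P), each = out_ch)])
  j_all <- rep(seq_len(P * out_ch), each = kc)
  nnz <- length(i_all)
  S0 <- Matrix::sparseMatrix(i = i_all, j = j_all, x = as.double(seq_len(nnz)),
                             dims = c(in_width * in_ch, P * out_ch))
  S_map <- as.integer(S0@x)   # slot s of S holds canonical weight S_map[s]
  St0 <- Matrix::t(S0)
  St_map <- as.integer(St0@x)
  list(type = "lc", in_width = in_width, in_ch = in_ch, kernel = kernel,
       stride = stride, P = P, out_ch = out_ch, kc = kc, win = win,
       S = S0, St = St0, S_map = S_map, St_map = St_map,
       w = numeric(nnz), b = numeric(P * out_ch))
}

lc_set_weights <- function(L, w) {
  w <- as.double(w)
  L$w <- w
  L$S@x <- w[L$S_map]
  L$St@x <- w[L$St_map]
  L
}

new_dense_layer <- function(fan_in, units, activation = "relu") {
  list(type = "dense", W = matrix(0, fan_in, units), b = numeric(units),
       activation = activation)
}

# He-style initialization, deterministic under the caller's RNG state
init_model_params <- function(model) {
  for (l in seq_along(model$lc)) {
    L <- model$lc[[l]]
    sd <- sqrt(2 / L$kc)
    model$lc[[l]] <- lc_set_weights(L, stats::rnorm(length(L$w), sd = sd))
  }
  for (l in seq_along(model$fc)) {
    L <- model$fc[[l]]
    model$fc[[l]]$W <- matrix(stats::rnorm(length(L$W), sd = sqrt(2 / nrow(L$W))),
                              nrow(L$W), ncol(L$W))
  }
  model$out$W <- matrix(stats::rnorm(length(model$out$W),
                                     sd = sqrt(1 / nrow(model$out$W))),
                        nrow(model$out$W), ncol(model$out$W))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass. X: B x input_width (already standardized); clinical: B x cw
# or NULL. Returns probs, logits and (if keep) the activation cache needed
# for backpropagation.
nn_forward <- function(model, X, clinical = NULL, training = FALSE,
                       keep = FALSE) {
  arch <- model$arch
  cache <- if (keep) list(lc = vector("list", length(model$lc)),
                          fc = vector("list", length(model$fc)))
  A <- X
  in_drop <- arch$input_dropout %||% 0
  if (training && in_drop > 0) {
    A <- A * matrix(stats::rbinom(length(A), 1L, 1 - in_drop) / (1 - in_drop),
                    nrow(A), ncol(A))
  }
  for (l in seq_along(model$lc)) {
    L <- model$lc[[l]]
    Z <- add_bias(as.matrix(A %*% L$S), L$b)
    if (keep) cache$lc[[l]] <- list(A_in = A, Z = Z)
    A <- pmax(Z, 0)
  }
  fused <- FALSE
  n_fc <- length(model$fc)
  for (l in seq_len(n_fc)) {
    if (arch$clinical_width > 0 && l == arch$fusion_point) {
      A <- cbind(A, clinical)
      fused <- TRUE
    }
    L <- model$fc[[l]]
    Z <- add_bias(A %*% L$W, L$b)
    H <- pmax(Z, 0)
    mask <- NULL
    if (training && arch$dropout_rate > 0) {
      mask <- matrix(
        stats::rbinom(length(H), 1L, 1 - arch$dropout_rate) / (1 - arch$dropout_rate),
        nrow(H), ncol(H))
      H <- H * mask
    }
    if (keep) cache$fc[[l]] <- list(A_in = A, Z = Z, mask = mask)
    A <- H
  }
  if (arch$clinical_width > 0 && !fused) {
    A <- cbind(A, clinical) # no interaction layers: fuse before the softmax layer
    fused <- TRUE
  }
  if (keep) cache$out_in <- A
  logits <- add_bias(A %*% model$out$W, model$out$b)
  list(probs = softmax_rows(logits), logits = logits, cache = cache)
}

# Backpropagation from d(loss)/d(logits). Returns gradients shaped like the
# parameters plus the gradient with respect to the (standardized) inputs,
# split into fingerprint and clinical parts.
nn_backward <- function(model, cache, dlogits) {
  arch <- model$arch
  cw <- arch$clinical_width
  grads <- list(lc = vector("list", length(model$lc)),
                fc = vector("list", length(model$fc)))
  A <- cache$out_in
  grads$out <- list(W = crossprod(A, dlogits), b = colSums(dlogits))
  dA <- tcrossprod(dlogits, model$out$W)
  d_clin <- NULL
  n_fc <- length(model$fc)
  if (cw > 0 && n_fc == 0) {
    nc <- ncol(dA)
    d_clin <- dA[, (nc - cw + 1):nc, drop = FALSE]
    dA <- dA[, seq_len(nc - cw), drop = FALSE]
  }
  for (l in rev(seq_len(n_fc))) {
    cc <- cache$fc[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- dA * (cc$Z > 0)
    grads$fc[[l]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, model$fc[[l]]$W)
    if (cw > 0 && l == arch$fusion_point) {
      nc <- ncol(dA)
      d_clin <- dA[, (nc - cw + 1):nc, drop = FALSE]
      dA <- dA[, seq_len(nc - cw), drop = FALSE]
    }
  }
  for (l in rev(seq_along(model$lc))) {
    L <- model$lc[[l]]
    cc <- cache$lc[[l]]
    dZ <- dA * (cc$Z > 0)
    gb <- colSums(dZ)
    gw <- numeric(length(L$w))
    seg <- L$kc * L$out_ch
    A_in <- cc$A_in
    for (p in seq_len(L$P)) {
      rows <- L$win[, p]
      cols <- (p - 1L) * L$out_ch + seq_len(L$out_ch)
      gw[((p - 1L) * seg + 1L):(p * seg)] <-
        crossprod(A_in[, rows, drop = FALSE], dZ[, cols, drop = FALSE])
    }
    grads$lc[[l]] <- list(w = gw, b = gb)
    dA <- as.matrix(dZ %*% L$St)
  }
  list(grads = grads, d_input = dA, d_clinical = d_clin)
}

# --- Adam optimizer over the model's parameter tensors ---------------------

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  st <- list(t = 0L,
             lc = lapply(model$lc, function(L) list(
               w = list(m = zero_like(L$w), v = zero_like(L$w)),
               b = list(m = zero_like(L$b), v = zero_like(L$b)))),
             fc = lapply(model$fc, function(L) list(
               W = list(m = zero_like(L$W), v = zero_like(L$W)),
               b = list(m = zero_like(L$b), v = zero_like(L$b)))),
             out = list(W = list(m = zero_like(model$out$W), v = zero_like(model$out$W)),
                        b = list(m = zero_like(model$out$b), v = zero_like(model$out$b))))
  st
}

adam_update <- function(param, grad, slot, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  slot$m <- beta1 * slot$m + (1 - beta1) * grad
  slot$v <- beta2 * slot$v + (1 - beta2) * grad^2
  mhat <- slot$m / (1 - beta1^t)
  vhat <- slot$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), slot = slot)
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in seq_along(model$lc)) {
    u <- adam_update(model$lc[[l]]$w, grads$lc[[l]]$w, state$lc[[l]]$w, lr, t)
    model$lc[[l]] <- lc_set_weights(model$lc[[l]], u$param)
    state$lc[[l]]$w <- u$slot
    u <- adam_update(model$lc[[l]]$b, grads$lc[[l]]$b, state$lc[[l]]$b, lr, t)
    model$lc[[l]]$b <- u$param
    state$lc[[l]]$b <- u$slot
  }
  for (l in seq_along(model$fc)) {
    u <- adam_update(model$fc[[l]]$W, grads$fc[[l]]$W, state$fc[[l]]$W, lr, t)
    model$fc[[l]]$W <- u$param
    state$fc[[l]]$W <- u$slot
    u <- adam_update(model$fc[[l]]$b, grads$fc[[l]]$b, state$fc[[l]]$b, lr, t)
    model$fc[[l]]$b <- u$param
    state$fc[[l]]$b <- u$slot
  }
  u <- adam_update(model$out$W, grads$out$W, state$out$W, lr, t)
  model$out$W <- u$param
  state$out$W <- u$slot
  u <- adam_update(model$out$b, grads$out$b, state$out$b, lr, t)
  model$out$b <- u$param
  state$out$b <- u$slot
  list(model = model, state = state)
}

# L2 penalty on weights (not biases)
add_weight_decay <- function(grads, model, wd) {
  for (l in seq_along(model$lc)) {
    grads$lc[[l]]$w <- grads$lc[[l]]$w + wd * model$lc[[l]]$w
  }
  for (l in seq_along(model$fc)) {
    grads$fc[[l]]$W <- grads$fc[[l]]$W + wd * model$fc[[l]]$W
  }
  grads$out$W <- grads$out$W + wd * model$out$W
  grads
}

snapshot_params <- function(model) {
  list(lc = lapply(model$lc, function(L) list(w = L$w, b = L$b)),
       fc = lapply(model$fc, function(L) list(W = L$W, b = L$b)),
       out = list(W = model$out$W, b = model$out$b))
}

restore_params <- function(model, snap) {
  for (l in seq_along(model$lc)) {
    model$lc[[l]] <- lc_set_weights(model$lc[[l]], snap$lc[[l]]$w)
    model$lc[[l]]$b <- snap$lc[[l]]$b
  }
  for (l in seq_along(model$fc)) {
    model$fc[[l]]$W <- snap$fc[[l]]$W
    model$fc[[l]]$b <- snap$fc[[l]]$b
  }
  model$out$W <- snap$out$W
  model$out$b <- snap$out$b
  model
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}
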