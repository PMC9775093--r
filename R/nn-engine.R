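# Minimal dense neural-network engine shared by the GCN modules, the
# fusion head and the baselines. Layers are either graph convolutions
# (Z = Ahat H W, no bias) or fully connected (Z = H W + b). LeakyReLU
# is applied after every layer except the last, which emits logits.
# Dropout (inverted scaling) is applied to the inputs of fully
# connected layers during training only.

leaky_relu <- function(Z, slope) {
  neg <- Z < 0
  Z[neg] <- Z[neg] * slope
  Z
}

leaky_relu_grad <- function(Z, slope) {
  G <- matrix(1, nrow(Z), ncol(Z))
  G[Z < 0] <- slope
  G
}

#' Numerically stable row-wise softmax
#' @param Z Matrix of logits, one row per sample.
#' @return Matrix of probabilities; rows sum to 1.
#' @export
softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

xavier_matrix <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

# layer_types: character vector "gconv"/"dense"; dims: length(types)+1
# Uses the current RNG state; callers seed it.
nn_init <- function(dims, layer_types, slope = 0.25, dropout_rate = 0.5) {
  stopifnot(length(dims) == length(layer_types) + 1)
  layers <- vector("list", length(layer_types))
  for (i in seq_along(layer_types)) {
    W <- xavier_matrix(dims[i], dims[i + 1])
    b <- if (layer_types[i] == "dense") numeric(dims[i + 1]) else NULL
    layers[[i]] <- list(type = layer_types[i], W = W, b = b)
  }
  list(layers = layers, slope = slope, dropout_rate = dropout_rate)
}

# Forward pass. Returns list(logits, cache) where cache[[i]] holds the
# layer input after dropout (Hin), the pre-activation Z and, for gconv
# layers, the propagated input P = Ahat %*% Hin.
nn_forward <- function(net, X, Ahat = NULL, training = FALSE) {
  H <- X
  L <- length(net$layers)
  cache <- vector("list", L)
  for (i in seq_len(L)) {
    layer <- net$layers[[i]]
    mask <- NULL
    if (layer$type == "dense" && training && net$dropout_rate > 0) {
      keep <- 1 - net$dropout_rate
      mask <- matrix(stats::rbinom(length(H), 1, keep) / keep,
                     nrow(H), ncol(H))
      H <- H * mask
    }
    if (layer$type == "gconv") {
      if (is.null(Ahat)) stop("graph convolution layer requires 'Ahat'")
      P <- Ahat %*% (H %*% layer$W)
      Z <- P
      Ain <- NULL
    } else {
      Z <- H %*% layer$W
      Z <- sweep(Z, 2, layer$b, "+")
      Ain <- H
    }
    cache[[i]] <- list(Hin = H, Ain = Ain, Z = Z, mask = mask)
    H <- if (i < L) leaky_relu(Z, net$slope) else Z
  }
  list(logits = unname(as.matrix(H)), cache = cache)
}

# Backward pass from dLogits (gradient of the loss w.r.t. the final
# pre-activation). Returns per-layer gradients and the gradient with
# respect to the network input (needed by the CNN front end).
nn_backward <- function(net, cache, dLogits, Ahat = NULL) {
  L <- length(net$layers)
  grads <- vector("list", L)
  G <- dLogits   # gradient w.r.t. Z of current layer
  dH <- NULL
  for (i in rev(seq_len(L))) {
    layer <- net$layers[[i]]
    cc <- cache[[i]]
    if (layer$type == "gconv") {
      # Z = Ahat (Hin W); Ahat symmetric
      AG <- crossprod(Ahat, G)            # t(Ahat) %*% G
      dW <- crossprod(cc$Hin, AG)
      dH <- AG %*% t(layer$W)
      db <- NULL
    } else {
      dW <- crossprod(cc$Hin, G)
      db <- colSums(G)
      dH <- G %*% t(layer$W)
      if (!is.null(cc$mask)) dH <- dH * cc$mask
    }
    grads[[i]] <- list(dW = dW, db = db)
    if (i > 1) {
      G <- dH * leaky_relu_grad(cache[[i - 1]]$Z, net$slope)
    }
  }
  list(layers = grads, dX = dH)
}

adam_init <- function(net) {
  list(t = 0, m = lapply(net$layers, function(l) {
    list(W = 0 * l$W, b = if (is.null(l$b)) NULL else 0 * l$b)
  }), v = lapply(net$layers, function(l) {
    list(W = 0 * l$W, b = if (is.null(l$b)) NULL else 0 * l$b)
  }))
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[paste0("d", p)]]
      if (is.null(g)) next
      opt$m[[i]][[p]] <- beta1 * opt$m[[i]][[p]] + (1 - beta1) * g
      opt$v[[i]][[p]] <- beta2 * opt$v[[i]][[p]] + (1 - beta2) * g^2
      mh <- opt$m[[i]][[p]] / bc1
      vh <- opt$v[[i]][[p]] / bc2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(net = net, opt = opt)
}

# Gradient of the (optionally sample-weighted) summed cross-entropy
# w.r.t. the logits: diag(w) (softmax(Z) - Y).
ce_logit_grad <- function(logits, Y_onehot, weights = NULL) {
  G <- softmax(logits) - Y_onehot
  if (!is.null(weights)) G <- G * weights
  G
}
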