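# Minimal fully connected network machinery used by the GAIN generator
# and discriminator: forward/backward passes with optional batch
# normalization on hidden layers, and SGD / momentum / Adam updates.
# Everything is plain base-R matrix algebra so training is bit-exactly
# reproducible from the seeded RNG stream.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Fan-in scaled uniform initialization; draws come from the caller's
# (already seeded) RNG stream.
mlp_init <- function(sizes, bn = FALSE) {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    lim <- sqrt(6 / fan_in)
    layer <- list(
      W = matrix(runif(fan_in * sizes[l + 1], -lim, lim), fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
    if (bn && l < L) { # hidden layers only
      layer$gamma <- rep(1, sizes[l + 1])
      layer$beta <- rep(0, sizes[l + 1])
      layer$run_mean <- rep(0, sizes[l + 1])
      layer$run_var <- rep(1, sizes[l + 1])
    }
    layers[[l]] <- layer
  }
  list(layers = layers, sizes = sizes, bn = bn)
}

act_forward <- function(y, activation) {
  switch(activation, relu = pmax(y, 0), tanh = tanh(y),
         abort(sprintf("unknown activation '%s'", activation)))
}

act_backward <- function(dh, y, h, activation) {
  switch(activation, relu = dh * (y > 0), tanh = dh * (1 - h^2))
}

# Forward pass returning output logits plus per-layer caches for
# backprop. In training mode BN uses batch statistics and updates the
# running estimates in place (the updated net is returned in the cache).
mlp_forward <- function(net, x, activation, training = TRUE) {
  L <- length(net$layers)
  caches <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    a <- h %*% ly$W + rep(ly$b, each = nrow(h))
    cache <- list(input = h, a = a)
    y <- a
    if (!is.null(ly$gamma)) {
      if (training) {
        mu <- colMeans(a)
        v <- colMeans(a^2) - mu^2
        net$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
        net$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      xhat <- sweep(sweep(a, 2, mu), 2, sqrt(v + BN_EPS), "/")
      y <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      cache$xhat <- xhat
      cache$inv_sd <- 1 / sqrt(v + BN_EPS)
    }
    cache$y <- y
    if (l < L) {
      h <- act_forward(y, activation)
      cache$h <- h
    } else {
      h <- y
    }
    caches[[l]] <- cache
  }
  list(logits = h, caches = caches, net = net)
}

# Backward pass from a gradient on the output logits. Returns parameter
# gradients (same shape as the layers) and the gradient on the input
# matrix (needed to push the adversarial signal through the
# discriminator into the generator output).
mlp_backward <- function(net, caches, dlogits, activation) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dh <- dlogits
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cache <- caches[[l]]
    dy <- if (l < L) act_backward(dh, cache$y, cache$h, activation) else dh
    if (!is.null(ly$gamma)) {
      b <- nrow(dy)
      dgamma <- colSums(dy * cache$xhat)
      dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, ly$gamma, "*")
      da <- sweep(
        b * dxhat - rep(colSums(dxhat), each = b) - cache$xhat * rep(dgamma, each = b),
        2, cache$inv_sd / b, "*"
      )
      grads[[l]] <- list(W = crossprod(cache$input, da), b = colSums(da),
                         gamma = dgamma, beta = dbeta)
    } else {
      da <- dy
      grads[[l]] <- list(W = crossprod(cache$input, da), b = colSums(da))
    }
    dh <- da %*% t(ly$W)
  }
  list(grads = grads, dinput = dh)
}

opt_init <- function(net) {
  lapply(net$layers, function(ly) {
    leaves <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    st <- lapply(ly[leaves], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

# One optimizer step; `t` is the 1-based update count (for Adam bias
# correction). Returns the updated net and optimizer state.
opt_step <- function(net, grads, state, optimizer, lr, t) {
  for (l in seq_along(net$layers)) {
    for (leaf in names(state[[l]])) {
      g <- grads[[l]][[leaf]]
      p <- net$layers[[l]][[leaf]]
      s <- state[[l]][[leaf]]
      if (optimizer == "sgd") {
        p <- p - lr * g
      } else if (optimizer == "momentum") {
        s$m <- 0.9 * s$m + g
        p <- p - lr * s$m
      } else if (optimizer == "adam") {
        s$m <- 0.9 * s$m + 0.1 * g
        s$v <- 0.999 * s$v + 0.001 * g^2
        mhat <- s$m / (1 - 0.9^t)
        vhat <- s$v / (1 - 0.999^t)
        p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
      } else {
        abort(sprintf("unknown optimizer '%s'", optimizer))
      }
      net$layers[[l]][[leaf]] <- p
      state[[l]][[leaf]] <- s
    }
  }
  list(net = net, state = state)
}

# Apply the generator's mixed output heads to raw logits: sigmoid on
# continuous columns, softmax within each categorical block.
output_heads <- function(logits, cont_cols, cat_blocks) {
  out <- logits
  if (length(cont_cols)) out[, cont_cols] <- plogis(logits[, cont_cols, drop = FALSE])
  for (blk in cat_blocks) {
    z <- logits[, blk, drop = FALSE]
    z <- exp(z - apply(z, 1, max))
    out[, blk] <- z / rowSums(z)
  }
  out
}

# Gradient of the heads: given dL/d(output activation), return
# dL/d(logit).
output_heads_backward <- function(dg, g, cont_cols, cat_blocks) {
  dlog <- dg
  if (length(cont_cols)) {
    gc <- g[, cont_cols, drop = FALSE]
    dlog[, cont_cols] <- dg[, cont_cols, drop = FALSE] * gc * (1 - gc)
  }
  for (blk in cat_blocks) {
    gb <- g[, blk, drop = FALSE]
    db <- dg[, blk, drop = FALSE]
    dot <- rowSums(db * gb)
    dlog[, blk] <- gb * (db - dot)
  }
  dlog
}
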