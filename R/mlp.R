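# Minimal multilayer-perceptron machinery: forward pass with caches,
# reverse-mode gradients (including gradients w.r.t. the input, needed for
# the deterministic policy gradient through the critic), and Adam.  Batch
# convention: rows are samples.

mlp_init <- function(sizes, out_act = c("linear", "tanh", "avgl1"),
                     act = "relu") {
  out_act <- match.arg(out_act)
  n_layer <- length(sizes) - 1L
  W <- vector("list", n_layer)
  b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))    # Glorot uniform
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes, act = act, out_act = out_act)
}

mlp_forward <- function(net, X, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  n_layer <- length(net$W)
  hs <- if (cache) vector("list", n_layer + 1L)
  if (cache) hs[[1]] <- X
  h <- X
  for (l in seq_len(n_layer)) {
    z <- h %*% net$W[[l]]
    z <- z + rep(net$b[[l]], each = nrow(z))
    if (l < n_layer) {
      h <- z * (z > 0)                     # relu
    } else {
      h <- switch(net$out_act,
                  linear = z,
                  tanh = tanh(z),
                  avgl1 = {
                    m <- rowMeans(abs(z)) + 1e-8
                    z / m
                  })
    }
    if (cache) hs[[l + 1L]] <- h
  }
  if (cache) list(out = h, hs = hs, z_last = if (net$out_act == "avgl1") z) else h
}

# dY: gradient of the loss w.r.t. the network output (same shape).
# Returns list(dW, db, dX).
mlp_backward <- function(net, fw, dY) {
  n_layer <- length(net$W)
  hs <- fw$hs
  dW <- vector("list", n_layer)
  db <- vector("list", n_layer)
  delta <- dY
  for (l in rev(seq_len(n_layer))) {
    h_out <- hs[[l + 1L]]
    if (l == n_layer) {
      if (net$out_act == "tanh") {
        delta <- delta * (1 - h_out^2)
      } else if (net$out_act == "avgl1") {
        z <- fw$z_last
        m <- rowMeans(abs(z)) + 1e-8
        k <- ncol(z)
        # f = z/m; df/dz = I/m - z sign(z)^T/(k m^2), applied per row
        s <- rowSums(delta * z)
        delta <- delta / m - sign(z) * (s / (k * m^2))
      }
    } else {
      delta <- delta * (h_out > 0)
    }
    dW[[l]] <- crossprod(hs[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- tcrossprod(delta, net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr = 3e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
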