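# Minimal dense-network engine used by the mixed-type VAE: tanh hidden
# layers, linear output layer, manual backpropagation, Adam updates.
# Each layer computes h = g(h_prev %*% W + b) with W of dim (in x out).
# All randomness is drawn from R's global RNG stream so a single set.seed
# upstream makes training bit-reproducible.

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    sd_l <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd_l),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

# forward pass; returns output and per-layer activations for backprop
.mlp_forward <- function(net, X) {
  L <- length(net$W)
  h <- vector("list", L + 1L)
  h[[1L]] <- X
  for (l in seq_len(L)) {
    a <- h[[l]] %*% net$W[[l]]
    a <- sweep(a, 2L, net$b[[l]], "+")
    h[[l + 1L]] <- if (l < L) tanh(a) else a
  }
  list(out = h[[L + 1L]], h = h)
}

# dOut: gradient of the loss w.r.t. the (linear) output, same dim as out
.mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (1 - cache$h[[l + 1L]]^2)  # tanh'
    dW[[l]] <- crossprod(cache$h[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

.adam_init <- function(net) {
  zero <- function(p) lapply(p, function(m) m * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

.adam_step <- function(net, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
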