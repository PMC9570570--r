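# Minimal fully connected network machinery: forward, backward, Adam.
# Layers are lists of (W: in x out, b: out); activations are "relu" or
# "linear". Softmax + cross-entropy is fused at the loss, so heads end in
# a linear layer and probabilities are produced by softmax_rows().

init_layers <- function(dims) {
  # He (fan-in scaled) normal initialization, biases at zero; draws come
  # from the caller's RNG stream.
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(W = matrix(stats::rnorm(fan_in * dims[l + 1L],
                                 sd = sqrt(2 / fan_in)),
                    fan_in, dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

forward_layers <- function(layers, acts, X) {
  A <- vector("list", length(layers) + 1L)
  A[[1L]] <- X
  for (l in seq_along(layers)) {
    Z <- A[[l]] %*% layers[[l]]$W
    Z <- sweep_add(Z, layers[[l]]$b)
    A[[l + 1L]] <- if (acts[l] == "relu") relu(Z) else Z
  }
  A
}

# adds bias row-vector b to every row of Z without sweep()'s overhead
sweep_add <- function(Z, b) Z + rep(b, each = nrow(Z))

relu <- function(Z) {
  Z[Z < 0] <- 0
  Z
}

softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)  # column-major recycling subtracts mx per row
  E / rowSums(E)
}

# Cross-entropy of row-probabilities P against integer labels y (1-based).
cross_entropy <- function(P, y) {
  p <- P[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

# Gradient of mean cross-entropy wrt the pre-softmax scores.
ce_score_grad <- function(P, y) {
  G <- P
  G[cbind(seq_along(y), y)] <- G[cbind(seq_along(y), y)] - 1
  G / nrow(P)
}

# Backpropagate dZ at the last layer's pre-activation through `layers`.
# Returns per-layer gradients and the gradient wrt the input matrix.
backward_layers <- function(layers, acts, A, dZ) {
  L <- length(layers)
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(A[[l]], dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- tcrossprod(dZ, layers[[l]]$W)
      dZ <- if (acts[l - 1L] == "relu") dA * (A[[l]] > 0) else dA
    } else {
      dZ <- tcrossprod(dZ, layers[[l]]$W)
    }
  }
  list(grads = grads, dX = dZ)
}

# Adam state keeps moment matrices that are mutated in place by the C++
# kernel; layers passed in must be private to the optimizer, so they are
# deep-copied here at state creation.
adam_state <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

# force an unshared copy of every parameter matrix so in-place updates
# cannot leak into other bindings
copy_layers <- function(layers) {
  lapply(layers, function(l) list(W = l$W + 0, b = l$b + 0))
}

# Plain (non-adaptive) gradient step, mutating in place; used for the
# adversarial ascent updates whose magnitude schedule must follow the
# transformed loss rather than Adam's normalized steps.
sgd_step <- function(layers, grads, lr, scale = 1) {
  for (l in seq_along(layers)) {
    .sgd_update(layers[[l]]$W, grads[[l]]$W, lr, scale)
    .sgd_update(layers[[l]]$b, grads[[l]]$b, lr, scale)
  }
  layers
}

grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g$W * g$W) + sum(g$b * g$b), 0)))
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, scale = 1, max_norm = Inf) {
  if (is.finite(max_norm)) {
    gn <- abs(scale) * grad_norm(grads)
    if (gn > max_norm) scale <- scale * (max_norm / gn)
  }
  state$t <- state$t + 1L
  for (l in seq_along(layers)) {
    .adam_update(layers[[l]]$W, state$m[[l]]$W, state$v[[l]]$W,
                 grads[[l]]$W, lr, beta1, beta2, eps, scale, state$t)
    .adam_update(layers[[l]]$b, state$m[[l]]$b, state$v[[l]]$b,
                 grads[[l]]$b, lr, beta1, beta2, eps, scale, state$t)
  }
  list(layers = layers, state = state)
}
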