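# Minimal dense-network machinery: forward pass, backpropagation and the
# Adam optimizer, written in base R matrix algebra.  Both the GAN and the
# multi-label DeepFM ride on these primitives.  Samples are rows; a layer
# stores W (fan_in x fan_out) and bias b (fan_out).

nn_init <- function(sizes) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 nrow = fan_in, ncol = sizes[l + 1L]),
      b = numeric(sizes[l + 1L])
    )
  }
  layers
}

# Forward pass with ReLU hidden layers and a linear output layer.
# With training = TRUE, inverted dropout is applied to hidden activations.
# Returns the output plus the caches backpropagation needs.
nn_forward <- function(layers, X, dropout = 0, training = FALSE) {
  X <- as_matrix_rows(X)
  nl <- length(layers)
  acts <- vector("list", nl + 1L)   # layer inputs (post-activation)
  zs <- vector("list", nl)          # pre-activations
  masks <- vector("list", nl)       # dropout masks on hidden activations
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    zs[[l]] <- Z
    if (l < nl) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(rbinom(length(A), 1L, 1 - dropout), nrow = nrow(A)) /
          (1 - dropout)
        A <- A * m
        masks[[l]] <- m
      }
    } else {
      A <- Z
    }
    acts[[l + 1L]] <- A
  }
  list(out = A, acts = acts, zs = zs, masks = masks)
}

# Backpropagate d(loss)/d(output) through the network.  Returns per-layer
# parameter gradients and the gradient with respect to the network input
# (needed when the generator receives gradients through the discriminator).
nn_backward <- function(layers, fwd, gout) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- gout
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], delta), b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
    if (l > 1L) {
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      delta <- delta * (fwd$zs[[l - 1L]] > 0)
    }
  }
  list(grads = grads, gin = delta)
}

# --- generic Adam over arbitrary nested lists of numeric arrays -----------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_init <- function(params) {
  list(t = 0L, m = tree_zero(params), v = tree_zero(params))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
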