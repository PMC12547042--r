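# Minimal feed-forward network core shared by the EDSS classifier and the
# Cox-loss risk network: dense layers, ReLU hidden activations, inverted
# dropout, L2 penalty on weights, hand-derived backprop, Adam updates.
# Sizes here are tiny (tens of units, thousands of rows), so plain R matrix
# algebra is entirely adequate.

net_init <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  n_layers <- length(dims) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    # He initialization, suited to ReLU units
    layers[[l]] <- list(
      W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                 nrow = dims[l], ncol = dims[l + 1L]),
      b = numeric(dims[l + 1L])
    )
  }
  layers
}

# Forward pass; hidden layers get ReLU (+ dropout when training), the final
# layer is returned as raw pre-activations (logits / risk scores).
net_forward <- function(net, x, dropout = 0, training = FALSE) {
  n_layers <- length(net)
  acts <- vector("list", n_layers + 1L)
  pre <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  acts[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% net[[l]]$W
    z <- sweep(z, 2L, net[[l]]$b, "+")
    pre[[l]] <- z
    if (l < n_layers) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        keep <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a))
        m <- keep / (1 - dropout)
        a <- a * m
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- z
    }
  }
  list(acts = acts, pre = pre, masks = masks, out = acts[[n_layers + 1L]])
}

# Backprop from d(loss)/d(final pre-activation); returns per-layer gradients.
net_backward <- function(net, cache, delta, l2 = 0) {
  n_layers <- length(net)
  grads <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(
      W = crossprod(cache$acts[[l]], delta) + l2 * net[[l]]$W,
      b = colSums(delta)
    )
    if (l > 1L) {
      delta <- delta %*% t(net[[l]]$W)
      if (!is.null(cache$masks[[l - 1L]])) delta <- delta * cache$masks[[l - 1L]]
      delta <- delta * (cache$pre[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(net) {
  list(t = 0L,
       m = lapply(net, function(l) list(W = 0 * l$W, b = 0 * l$b)),
       v = lapply(net, function(l) list(W = 0 * l$W, b = 0 * l$b)))
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / c1
      vhat <- state$v[[l]][[p]] / c2
      net[[l]][[p]] <- net[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# L2 penalty term (weights only, not biases)
net_l2_penalty <- function(net, l2) {
  if (l2 <= 0) return(0)
  l2 / 2 * sum(vapply(net, function(l) sum(l$W^2), numeric(1L)))
}
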