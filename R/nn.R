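# Minimal fully connected neural-network machinery in base R matrix code:
# ReLU stacks with a shared trunk and routed output heads (per feature, per
# participant-cluster, or both), trained with Adam. Used by the baseline
# regressors, the direct generators and the conditional GANs.

nn_layers_new <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fan_in <- sizes[i]
    list(W = matrix(stats::rnorm(fan_in * sizes[i + 1L], 0,
                                 sqrt(2 / fan_in)),
                    fan_in, sizes[i + 1L]),
         b = rep(0, sizes[i + 1L]))
  })
}

# Forward pass; hidden layers ReLU, last layer linear. Returns activations
# for backprop.
nn_layers_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

# Backward pass given dL/d(output); returns per-layer grads and dL/d(input).
nn_layers_backward <- function(layers, acts, dout) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (acts[[l + 1L]] > 0)
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                      b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

nn_adam_new <- function(layers) {
  lapply(layers, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW <- s$mW / (1 - beta1^t); vW <- s$vW / (1 - beta2^t)
    mb <- s$mb / (1 - beta1^t); vb <- s$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mW / (sqrt(vW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mb / (sqrt(vb) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# A multitask network: shared trunk plus heads routed by cluster (rows),
# feature (output columns), or both. head_map is a data.frame with columns
# cluster (NA = all rows) and feature (NA = all output columns).
mt_new <- function(input_dim, output_dim, trunk_sizes, head_hidden,
                   clusters = NULL, per_feature = FALSE) {
  cl <- if (is.null(clusters)) NA_integer_ else clusters
  ft <- if (per_feature) seq_len(output_dim) else NA_integer_
  head_map <- expand.grid(cluster = cl, feature = ft)
  trunk <- nn_layers_new(c(input_dim, trunk_sizes))
  trunk_out <- trunk_sizes[length(trunk_sizes)]
  heads <- lapply(seq_len(nrow(head_map)), function(i) {
    out_dim <- if (is.na(head_map$feature[i])) output_dim else 1L
    nn_layers_new(c(trunk_out, head_hidden, out_dim))
  })
  list(trunk = trunk, heads = heads, head_map = head_map,
       input_dim = input_dim, output_dim = output_dim)
}

mt_forward <- function(model, X, cluster_ids = NULL) {
  tacts <- nn_layers_forward(model$trunk, X)
  H <- tacts[[length(tacts)]]
  out <- matrix(0, nrow(X), model$output_dim)
  hacts <- vector("list", length(model$heads))
  hrows <- vector("list", length(model$heads))
  for (i in seq_along(model$heads)) {
    cl <- model$head_map$cluster[i]
    ft <- model$head_map$feature[i]
    rows <- if (is.na(cl)) seq_len(nrow(X)) else which(cluster_ids == cl)
    if (!length(rows)) { hrows[[i]] <- integer(0); next }
    a <- nn_layers_forward(model$heads[[i]], H[rows, , drop = FALSE])
    o <- a[[length(a)]]
    if (is.na(ft)) out[rows, ] <- o else out[rows, ft] <- o
    hacts[[i]] <- a
    hrows[[i]] <- rows
  }
  list(out = out, tacts = tacts, hacts = hacts, hrows = hrows)
}

mt_backward <- function(model, fwd, dout) {
  H <- fwd$tacts[[length(fwd$tacts)]]
  dH <- H * 0
  head_grads <- vector("list", length(model$heads))
  for (i in seq_along(model$heads)) {
    rows <- fwd$hrows[[i]]
    if (!length(rows)) {
      head_grads[[i]] <- lapply(model$heads[[i]], function(p)
        list(W = p$W * 0, b = p$b * 0))
      next
    }
    ft <- model$head_map$feature[i]
    d <- if (is.na(ft)) dout[rows, , drop = FALSE] else
      dout[rows, ft, drop = FALSE]
    bk <- nn_layers_backward(model$heads[[i]], fwd$hacts[[i]], d)
    head_grads[[i]] <- bk$grads
    dH[rows, ] <- dH[rows, ] + bk$dX
  }
  tb <- nn_layers_backward(model$trunk, fwd$tacts, dH)
  list(trunk = tb$grads, heads = head_grads, dX = tb$dX)
}

mt_adam_new <- function(model) {
  list(trunk = nn_adam_new(model$trunk),
       heads = lapply(model$heads, nn_adam_new))
}

mt_adam_step <- function(model, grads, state, lr, t) {
  up <- nn_adam_step(model$trunk, grads$trunk, state$trunk, lr, t)
  model$trunk <- up$layers; state$trunk <- up$state
  for (i in seq_along(model$heads)) {
    up <- nn_adam_step(model$heads[[i]], grads$heads[[i]],
                       state$heads[[i]], lr, t)
    model$heads[[i]] <- up$layers
    state$heads[[i]] <- up$state
  }
  list(model = model, state = state)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
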