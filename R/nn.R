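# Parameter initialization, layer helpers and the SGD optimizer used by the
# equivariant network. Parameters live in a flat named list of matrices; a
# forward pass wraps them in tape leaves (see autodiff.R).

init_linear <- function(params, name, fan_in, fan_out, zero = FALSE) {
  if (zero) {
    W <- matrix(0, fan_in, fan_out)
    b <- rep(0, fan_out)
  } else {
    s <- 1 / sqrt(fan_in)
    W <- matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
    b <- stats::runif(fan_out, -s, s)
  }
  params[[paste0(name, "_W")]] <- W
  params[[paste0(name, "_b")]] <- matrix(b, nrow = 1L)
  params
}

nn_linear <- function(pl, name, x, act = "none") {
  out <- ad_add_bias(ad_matmul(x, pl[[paste0(name, "_W")]]),
                     pl[[paste0(name, "_b")]])
  switch(act,
         none = out,
         relu = ad_relu(out),
         sigmoid = ad_sigmoid(out))
}

# two-layer perceptron: linear-relu-linear(-act)
nn_mlp <- function(pl, name, x, act_out = "none") {
  h <- nn_linear(pl, paste0(name, "1"), x, act = "relu")
  nn_linear(pl, paste0(name, "2"), h, act = act_out)
}

# Neighborhood gather indices for 3x3 convolution on an L x L grid whose
# pairs are flattened column-major (row index r = i + (j-1) L). Out-of-grid
# neighbors point at the zero padding row L^2 + 1.
conv3x3_indices <- function(L) {
  i <- rep(seq_len(L), L)
  j <- rep(seq_len(L), each = L)
  pad <- L * L + 1L
  cols <- list()
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      ii <- i + di
      jj <- j + dj
      ok <- ii >= 1L & ii <= L & jj >= 1L & jj <= L
      idx <- rep(pad, L * L)
      idx[ok] <- ii[ok] + (jj[ok] - 1L) * L
      cols[[k]] <- idx
    }
  }
  do.call(cbind, cols)
}

# 3x3 same-padding convolution via im2col gathers + one matmul.
# x: (L^2 x C) pair features; idx: from conv3x3_indices(L).
nn_conv3x3 <- function(pl, name, x, idx, act = "none") {
  xp <- ad_pad0(x)
  patches <- do.call(ad_cbind, lapply(seq_len(ncol(idx)), function(k) {
    ad_gather(xp, idx[, k])
  }))
  nn_linear(pl, name, patches, act = act)
}

# SGD with classical momentum and L2 weight decay, matching the training
# regime: v <- mu v + (g + wd p); p <- p - lr v. Gradients are optionally
# clipped to a global norm before the update (stabilizes the stiff
# coordinate-update pathway at desk-scale learning rates).
sgd_state <- function() list()

# Adam optimizer: per-parameter adaptive step sizes. Used for desk-scale
# smoke/overfit runs where heterogeneous loss-term gradient scales make
# plain SGD impractically slow; full-scale training keeps the published
# SGD regime.
adam_state <- function() list(t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 5e-5, clip_norm = NULL) {
  if (!is.null(clip_norm)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) {
      if (is.null(g)) 0 else sum(g^2)
    }, numeric(1))))
    if (is.finite(gnorm) && gnorm > clip_norm) {
      grads <- lapply(grads, function(g) {
        if (is.null(g)) NULL else g * (clip_norm / gnorm)
      })
    }
  }
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * params[[nm]]
    m <- state[[paste0(nm, ".m")]]
    v <- state[[paste0(nm, ".v")]]
    if (is.null(m)) { m <- array(0, dim(params[[nm]])); v <- m }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0(nm, ".m")]] <- m
    state[[paste0(nm, ".v")]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 5e-5, clip_norm = NULL) {
  if (!is.null(clip_norm)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) {
      if (is.null(g)) 0 else sum(g^2)
    }, numeric(1))))
    if (is.finite(gnorm) && gnorm > clip_norm) {
      grads <- lapply(grads, function(g) {
        if (is.null(g)) NULL else g * (clip_norm / gnorm)
      })
    }
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * params[[nm]]
    v <- state[[nm]]
    if (is.null(v)) v <- array(0, dim(params[[nm]]))
    v <- momentum * v + g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, state = state)
}
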