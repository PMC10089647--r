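# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The equivariant network is trained end-to-end, so every forward pass
# records its operations on a tape; ad_backward() replays the tape in
# reverse, accumulating vector-Jacobian products. Values are plain numeric
# matrices (vectors are n x 1). This is internal machinery: only the
# network module uses it.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "ad_tape"
  t
}

ad_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- NULL
  nd$vjp <- NULL
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_op <- function(value, parents, vjp) {
  nd <- ad_leaf(parents[[1]]$tape, value)
  nd$parents <- parents
  nd$vjp <- vjp
  nd
}

# Reverse sweep: seeds the root with gradient 1 and accumulates into leaves.
ad_backward <- function(tape, root) {
  root$grad <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- ps[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
}

ad_add <- function(a, b) {
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# add a bias row-vector (length = ncol) to every row
ad_add_bias <- function(a, b) {
  ad_op(sweep(a$value, 2, as.numeric(b$value), "+"), list(a, b),
        function(g) list(g, colSums(g)))
}

ad_mul <- function(a, b) {
  ad_op(a$value * b$value, list(a, b),
        function(g) list(g * b$value, g * a$value))
}

# multiply by a constant scalar or conformable constant array
ad_cmul <- function(a, k) {
  ad_op(a$value * k, list(a), function(g) list(g * k))
}

ad_matmul <- function(a, b) {
  ad_op(a$value %*% b$value, list(a, b),
        function(g) list(g %*% t(b$value), crossprod(a$value, g)))
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_op(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_square <- function(a) {
  ad_op(a$value^2, list(a), function(g) list(2 * g * a$value))
}

ad_sqrt <- function(a, eps = 1e-12) {
  s <- sqrt(a$value + eps)
  ad_op(s, list(a), function(g) list(g * 0.5 / s))
}

ad_rowsums <- function(a) {
  nc <- ncol(a$value)
  ad_op(matrix(rowSums(a$value), ncol = 1L), list(a),
        function(g) list(matrix(g, nrow(g), nc)))
}

ad_sum <- function(a) {
  dm <- dim(a$value)
  ad_op(sum(a$value), list(a), function(g) list(array(g, dm)))
}

ad_mean <- function(a) {
  n <- length(a$value)
  dm <- dim(a$value)
  ad_op(mean(a$value), list(a), function(g) list(array(g / n, dm)))
}

# row gather: out[r, ] = a[idx[r], ]
ad_gather <- function(a, idx) {
  nr <- nrow(a$value)
  ad_op(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# row scatter-sum into n rows: out[i, ] = sum over r with idx[r] == i of a[r, ]
ad_scatter <- function(a, idx, n) {
  val <- matrix(0, n, ncol(a$value))
  acc <- rowsum(a$value, idx)
  val[as.integer(rownames(acc)), ] <- acc
  ad_op(val, list(a), function(g) list(g[idx, , drop = FALSE]))
}

ad_cbind <- function(...) {
  nodes <- list(...)
  ncols <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(ncols)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_op(do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
        function(g) {
          lapply(seq_along(nodes), function(i) {
            g[, starts[i]:ends[i], drop = FALSE]
          })
        })
}

ad_cols <- function(a, j) {
  nc <- ncol(a$value)
  ad_op(a$value[, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, j] <- g
    list(out)
  })
}

# scale each row i by constant v[i]
ad_rowscale <- function(a, v) {
  ad_op(a$value * v, list(a), function(g) list(g * v))
}

# append one zero row (padding target for convolution gathers)
ad_pad0 <- function(a) {
  n <- nrow(a$value)
  ad_op(rbind(a$value, 0), list(a),
        function(g) list(g[seq_len(n), , drop = FALSE]))
}

# add a constant scalar or conformable constant array
ad_cadd <- function(a, k) {
  ad_op(a$value + k, list(a), function(g) list(g))
}

# replicate an n x 1 column to n x k
ad_colrep <- function(a, k) {
  ad_op(matrix(a$value, nrow(a$value), k), list(a),
        function(g) list(matrix(rowSums(g), ncol = 1L)))
}

ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_op(s, list(a), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

# mean categorical cross-entropy of row-wise logits against integer classes
ad_ce_logits <- function(a, classes) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  val <- -mean(log(pmax(p[cbind(seq_len(n), classes)], 1e-300)))
  ad_op(val, list(a), function(g) {
    oh <- matrix(0, n, ncol(p))
    oh[cbind(seq_len(n), classes)] <- 1
    list(g * (p - oh) / n)
  })
}

# log-odds of a probability, clamped away from 0/1
ad_logit <- function(a, eps = 1e-4) {
  p <- pmin(pmax(a$value, eps), 1 - eps)
  inside <- a$value > eps & a$value < 1 - eps
  ad_op(log(p / (1 - p)), list(a),
        function(g) list(g * inside / (p * (1 - p))))
}

ad_tanh <- function(a) {
  t <- tanh(a$value)
  ad_op(t, list(a), function(g) list(g * (1 - t^2)))
}
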