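# Minimal tape-based reverse-mode differentiation over base-R matrices.
#
# Every forward pass builds a fresh tape; nodes are environments holding the
# value, accumulated gradient and a closure that pushes gradients to the
# node's parents. backward() walks the tape in reverse creation order, which
# is a valid reverse topological order because operands always precede their
# results. Gradients are exact (validated against central finite differences
# in the test suite).

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- new.env(parent = emptyenv())
  tp
}

node_new <- function(tape, val, backfn = NULL, pname = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- backfn
  nd$pname <- pname
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

accum_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

tp_const <- function(tape, v) node_new(tape, v)

# One leaf per parameter per tape; repeated requests return the cached node
# so gradients from all uses accumulate in one place.
tp_param <- function(tape, name, v) {
  if (!is.null(tape$params[[name]])) return(tape$params[[name]])
  nd <- node_new(tape, v, pname = name)
  tape$params[[name]] <- nd
  nd
}

tp_matmul <- function(tape, a, b) {
  nd <- node_new(tape, a$val %*% b$val)
  nd$backfn <- function(g) {
    accum_grad(a, g %*% t(b$val))
    accum_grad(b, t(a$val) %*% g)
  }
  nd
}

# a %*% t(b), used for attention scores
tp_matmul_t <- function(tape, a, b) {
  nd <- node_new(tape, a$val %*% t(b$val))
  nd$backfn <- function(g) {
    accum_grad(a, g %*% b$val)
    accum_grad(b, t(g) %*% a$val)
  }
  nd
}

# Addition; b may be a 1-row bias broadcast over the rows of a.
tp_add <- function(tape, a, b) {
  broadcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  v <- if (broadcast) sweep(a$val, 2L, as.numeric(b$val), "+") else a$val + b$val
  nd <- node_new(tape, v)
  nd$backfn <- function(g) {
    accum_grad(a, g)
    accum_grad(b, if (broadcast) matrix(colSums(g), 1L) else g)
  }
  nd
}

tp_mul <- function(tape, a, b) {
  nd <- node_new(tape, a$val * b$val)
  nd$backfn <- function(g) {
    accum_grad(a, g * b$val)
    accum_grad(b, g * a$val)
  }
  nd
}

# Elementwise constant affine map: a * mult + shift
tp_affine <- function(tape, a, mult = 1, shift = 0) {
  nd <- node_new(tape, a$val * mult + shift)
  nd$backfn <- function(g) accum_grad(a, g * mult)
  nd
}

tp_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  nd <- node_new(tape, s)
  nd$backfn <- function(g) accum_grad(a, g * s * (1 - s))
  nd
}

tp_tanh <- function(tape, a) {
  s <- tanh(a$val)
  nd <- node_new(tape, s)
  nd$backfn <- function(g) accum_grad(a, g * (1 - s^2))
  nd
}

tp_relu <- function(tape, a) {
  m <- a$val > 0
  nd <- node_new(tape, a$val * m)
  nd$backfn <- function(g) accum_grad(a, g * m)
  nd
}

# Row-wise softmax of (a + mask); mask is a constant additive matrix
# (0 within an attention block, a large negative value outside it).
tp_softmax_masked <- function(tape, a, mask = NULL) {
  z <- if (is.null(mask)) a$val else a$val + mask
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  nd <- node_new(tape, p)
  nd$backfn <- function(g) accum_grad(a, p * (g - rowSums(g * p)))
  nd
}

tp_rows <- function(tape, a, idx) {
  nd <- node_new(tape, a$val[idx, , drop = FALSE])
  nd$backfn <- function(g) {
    gg <- rowsum(g, group = idx)
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[as.integer(rownames(gg)), ] <- gg
    accum_grad(a, ga)
  }
  nd
}

tp_cols <- function(tape, a, jdx) {
  nd <- node_new(tape, a$val[, jdx, drop = FALSE])
  nd$backfn <- function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[, jdx] <- g
    accum_grad(a, ga)
  }
  nd
}

tp_cbind2 <- function(tape, a, b) {
  ka <- ncol(a$val)
  nd <- node_new(tape, cbind(a$val, b$val))
  nd$backfn <- function(g) {
    accum_grad(a, g[, seq_len(ka), drop = FALSE])
    accum_grad(b, g[, -seq_len(ka), drop = FALSE])
  }
  nd
}

# (B*steps) x d instance-major sequence -> B x (steps*d) flat matrix
tp_flatten_steps <- function(tape, a, n_batch, steps) {
  d <- ncol(a$val)
  v <- matrix(0, n_batch, steps * d)
  for (t in seq_len(steps))
    v[, (t - 1L) * d + seq_len(d)] <- a$val[(seq_len(n_batch) - 1L) * steps + t, , drop = FALSE]
  nd <- node_new(tape, v)
  nd$backfn <- function(g) {
    ga <- matrix(0, nrow(a$val), d)
    for (t in seq_len(steps))
      ga[(seq_len(n_batch) - 1L) * steps + t, ] <- g[, (t - 1L) * d + seq_len(d), drop = FALSE]
    accum_grad(a, ga)
  }
  nd
}

tp_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, as.numeric(gamma$val), "*")
  out <- sweep(out, 2L, as.numeric(beta$val), "+")
  nd <- node_new(tape, out)
  nd$backfn <- function(g) {
    dxhat <- sweep(g, 2L, as.numeric(gamma$val), "*")
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dx <- inv * (dxhat - s1 / d - xhat * s2 / d)
    accum_grad(a, dx)
    accum_grad(gamma, matrix(colSums(g * xhat), 1L))
    accum_grad(beta, matrix(colSums(g), 1L))
  }
  nd
}

# Fused softmax + mean binary cross-entropy over 2-column logits.
# y is a 0/1 vector; returns a scalar-valued node.
tp_softmax_ce <- function(tape, logits, y, eps = 1e-7) {
  z <- logits$val - apply(logits$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  p1 <- pmin(pmax(p[, 2L], eps), 1 - eps)
  loss <- -mean(y * log(p1) + (1 - y) * log(1 - p1))
  nd <- node_new(tape, loss)
  nd$backfn <- function(g) {
    hot <- cbind(1 - y, y)
    accum_grad(logits, g * (p - hot) / n)
  }
  nd
}

# Margin contrastive loss over paired representation rows (same-class pairs
# have y = 1): (1/2N) sum (1-y) D^2 + y max(margin - D, 0)^2, with D the
# cosine similarity of each row pair.
tp_contrastive <- function(tape, a, b, y, margin = 2) {
  A <- a$val; B <- b$val
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  dot <- rowSums(A * B)
  D <- dot / (na * nb)
  m <- pmax(margin - D, 0)
  n <- nrow(A)
  loss <- sum((1 - y) * D^2 + y * m^2) / (2 * n)
  nd <- node_new(tape, loss)
  nd$backfn <- function(g) {
    dLdD <- ((1 - y) * D - y * m) / n
    ga <- (B / (na * nb) - (D / na^2) * A) * dLdD * g
    gb <- (A / (na * nb) - (D / nb^2) * B) * dLdD * g
    accum_grad(a, ga)
    accum_grad(b, gb)
  }
  nd
}

# Weighted scalar sum of loss nodes (both scalar-valued).
tp_axpy <- function(tape, a, b, wa, wb) {
  nd <- node_new(tape, wa * a$val + wb * b$val)
  nd$backfn <- function(g) {
    accum_grad(a, g * wa)
    accum_grad(b, g * wb)
  }
  nd
}

# Seed the root gradient and sweep the tape in reverse; returns a named list
# of parameter gradients.
backward <- function(tape, root) {
  root$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  grads <- list()
  for (name in ls(tape$params)) {
    g <- tape$params[[name]]$grad
    if (is.null(g)) g <- matrix(0, nrow(tape$params[[name]]$val),
                                ncol(tape$params[[name]]$val))
    grads[[name]] <- g
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

# Updates only the parameters named in `active`; everything else is left
# bit-identical (the freezing contract).
adam_step <- function(params, grads, state, active, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (name in active) {
    g <- grads[[name]]
    if (is.null(g)) next
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g^2
    mhat <- state$m[[name]] / (1 - beta1^t)
    vhat <- state$v[[name]] / (1 - beta2^t)
    params[[name]] <- params[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
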