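# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records every intermediate value together with a backward closure;
# `tp_backward()` walks the tape in reverse and accumulates gradients.
# This is deliberately small: only the operations needed by the graph
# encoders, the fusion head, the losses, and integrated gradients are
# provided. All values are plain numeric matrices.

tape_new <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

tp_push <- function(tape, value, parents = integer(0), backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, backward = backward)
  tape$n <- n
  n
}

tp_value <- function(tape, id) {
  force(id)  # `id` may be a nested op call that still has to push its node
  tape$nodes[[id]]$value
}

# Leaf node. Constants and variables are identical on the forward pass;
# gradients simply accumulate at every leaf that is reachable.
tp_leaf <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  tp_push(tape, value)
}

#' @noRd
tp_backward <- function(tape, loss_id) {
  grads <- vector("list", tape$n)
  v <- tp_value(tape, loss_id)
  grads[[loss_id]] <- matrix(1, nrow(v), ncol(v))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

tp_matmul <- function(tape, a, b) {
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  tp_push(tape, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), t(A) %*% g)
  })
}

# Addition with limited broadcasting: b may be a 1 x ncol(a) bias row or a
# 1 x 1 scalar.
tp_add <- function(tape, a, b) {
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  if (identical(dim(A), dim(B))) {
    tp_push(tape, A + B, c(a, b), function(g) list(g, g))
  } else if (nrow(B) == 1L && ncol(B) == ncol(A)) {
    tp_push(tape, sweep(A, 2L, B[1L, ], "+"), c(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else if (nrow(B) == 1L && ncol(B) == 1L) {
    tp_push(tape, A + B[1L, 1L], c(a, b), function(g) {
      list(g, matrix(sum(g), 1L, 1L))
    })
  } else {
    stop("tp_add: incompatible shapes ", paste(dim(A), collapse = "x"),
         " and ", paste(dim(B), collapse = "x"))
  }
}

tp_sub <- function(tape, a, b) {
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  stopifnot(identical(dim(A), dim(B)))
  tp_push(tape, A - B, c(a, b), function(g) list(g, -g))
}

tp_mul <- function(tape, a, b) {
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  stopifnot(identical(dim(A), dim(B)))
  tp_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_scale <- function(tape, a, s) {
  A <- tp_value(tape, a)
  tp_push(tape, A * s, a, function(g) list(g * s))
}

tp_relu <- function(tape, a) {
  A <- tp_value(tape, a)
  tp_push(tape, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tp_leaky_relu <- function(tape, a, slope = 0.2) {
  A <- tp_value(tape, a)
  tp_push(tape, ifelse(A > 0, A, slope * A), a, function(g) {
    list(g * ifelse(A > 0, 1, slope))
  })
}

tp_sigmoid <- function(tape, a) {
  A <- tp_value(tape, a)
  S <- 1 / (1 + exp(-A))
  tp_push(tape, S, a, function(g) list(g * S * (1 - S)))
}

tp_tanh <- function(tape, a) {
  Th <- tanh(tp_value(tape, a))
  tp_push(tape, Th, a, function(g) list(g * (1 - Th^2)))
}

tp_identity_act <- function(tape, a) a

tp_activation <- function(tape, a, name, slope = 0.2) {
  switch(name,
    relu = tp_relu(tape, a),
    leaky_relu = tp_leaky_relu(tape, a, slope),
    sigmoid = tp_sigmoid(tape, a),
    tanh = tp_tanh(tape, a),
    identity = a,
    stop("unknown activation: ", name)
  )
}

# Row gather: value is a[idx, ]. Backward scatter-adds into the source rows.
tp_rows <- function(tape, a, idx) {
  A <- tp_value(tape, a)
  idx <- as.integer(idx)
  tp_push(tape, A[idx, , drop = FALSE], a, function(g) {
    gA <- matrix(0, nrow(A), ncol(A))
    agg <- rowsum(g, group = idx)
    gA[as.integer(rownames(agg)), ] <- agg
    list(gA)
  })
}

tp_rbind <- function(tape, ids) {
  vals <- lapply(ids, tp_value, tape = tape)
  nr <- vapply(vals, nrow, integer(1))
  tp_push(tape, do.call(rbind, vals), as.integer(ids), function(g) {
    ends <- cumsum(nr)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(ids), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

tp_cbind <- function(tape, ids) {
  vals <- lapply(ids, tp_value, tape = tape)
  nc <- vapply(vals, ncol, integer(1))
  tp_push(tape, do.call(cbind, vals), as.integer(ids), function(g) {
    ends <- cumsum(nc)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(ids), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

tp_mean_rows <- function(tape, a) {
  A <- tp_value(tape, a)
  n <- nrow(A)
  tp_push(tape, matrix(colMeans(A), 1L), a, function(g) {
    list(matrix(rep(g / n, each = n), n, ncol(A)))
  })
}

tp_sum_rows <- function(tape, a) {
  A <- tp_value(tape, a)
  n <- nrow(A)
  tp_push(tape, matrix(colSums(A), 1L), a, function(g) {
    list(matrix(rep(g, each = n), n, ncol(A)))
  })
}

tp_sum_all <- function(tape, a) {
  A <- tp_value(tape, a)
  tp_push(tape, matrix(sum(A), 1L, 1L), a, function(g) {
    list(matrix(g[1L, 1L], nrow(A), ncol(A)))
  })
}

# Softmax over segments of a column vector of logits. `groups` assigns each
# entry to a segment; normalization happens within each segment.
tp_segment_softmax <- function(tape, a, groups) {
  A <- tp_value(tape, a)
  stopifnot(ncol(A) == 1L, length(groups) == nrow(A))
  groups <- as.integer(groups)
  x <- A[, 1L]
  mx <- tapply(x, groups, max)[as.character(groups)]
  ex <- exp(x - mx)
  den <- tapply(ex, groups, sum)[as.character(groups)]
  y <- ex / den
  tp_push(tape, matrix(y, ncol = 1L), a, function(g) {
    gy <- g[, 1L] * y
    dot <- tapply(gy, groups, sum)[as.character(groups)]
    list(matrix(gy - y * dot, ncol = 1L))
  })
}

# Segment sum: aggregates rows of `a` into `ngroups` output rows.
tp_segment_sum <- function(tape, a, groups, ngroups) {
  A <- tp_value(tape, a)
  groups <- as.integer(groups)
  out <- matrix(0, ngroups, ncol(A))
  agg <- rowsum(A, group = groups)
  out[as.integer(rownames(agg)), ] <- agg
  tp_push(tape, out, a, function(g) list(g[groups, , drop = FALSE]))
}

# Broadcast multiply of a column vector (E x 1) against every column of a
# matrix (E x d); used to scale per-edge messages by attention weights.
tp_colmul <- function(tape, col, mat) {
  Cv <- tp_value(tape, col); M <- tp_value(tape, mat)
  stopifnot(ncol(Cv) == 1L, nrow(Cv) == nrow(M))
  cvec <- Cv[, 1L]
  tp_push(tape, M * cvec, c(col, mat), function(g) {
    list(matrix(rowSums(g * M), ncol = 1L), g * cvec)
  })
}

# Inverted dropout; the mask is fixed at call time so the forward value and
# the backward pass stay consistent.
tp_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  A <- tp_value(tape, a)
  mask <- matrix(stats::rbinom(length(A), 1L, 1 - rate), nrow(A)) / (1 - rate)
  tp_push(tape, A * mask, a, function(g) list(g * mask))
}

# Mean squared error against a constant target column.
tp_mse_loss <- function(tape, pred, y) {
  P <- tp_value(tape, pred)
  stopifnot(length(y) == nrow(P))
  d <- P[, 1L] - y
  n <- length(y)
  tp_push(tape, matrix(mean(d^2), 1L, 1L), pred, function(g) {
    list(matrix(g[1L, 1L] * 2 * d / n, ncol = 1L))
  })
}

# Numerically stable binary cross-entropy on logits.
tp_bce_logits_loss <- function(tape, logits, y) {
  Z <- tp_value(tape, logits)
  stopifnot(length(y) == nrow(Z))
  z <- Z[, 1L]
  n <- length(y)
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  tp_push(tape, matrix(loss, 1L, 1L), logits, function(g) {
    list(matrix(g[1L, 1L] * (p - y) / n, ncol = 1L))
  })
}

# Gated recurrent unit update h' = (1-z)*h + z*htilde, composed from tape
# primitives so its gradient comes for free. `m` is the message, `h` the
# previous state, both N x d node ids; `p` holds the parameter node ids.
tp_gru <- function(tape, m, h, p) {
  zt <- tp_sigmoid(tape, tp_add(tape, tp_add(tape,
    tp_matmul(tape, m, p$Wz), tp_matmul(tape, h, p$Uz)), p$bz))
  rt <- tp_sigmoid(tape, tp_add(tape, tp_add(tape,
    tp_matmul(tape, m, p$Wr), tp_matmul(tape, h, p$Ur)), p$br))
  ht <- tp_tanh(tape, tp_add(tape, tp_add(tape,
    tp_matmul(tape, m, p$Wh), tp_matmul(tape, tp_mul(tape, rt, h), p$Uh)),
    p$bh))
  one <- tp_leaf(tape, matrix(1, nrow(tp_value(tape, zt)),
                              ncol(tp_value(tape, zt))))
  tp_add(tape, tp_mul(tape, tp_sub(tape, one, zt), h),
         tp_mul(tape, zt, ht))
}
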