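# Minimal reverse-mode tape used by the end-to-end model. Values are base R
# matrices; each op pushes a node holding the forward value and a closure that
# accumulates gradients into its parents. The public encoder/fusion functions
# are plain-matrix forwards; equivalence of the two paths is asserted in the
# test suite. All internal.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$val <- vector("list", 128L)
  tp$bw <- vector("list", 128L)
  tp$grad <- NULL
  tp
}

tp_push <- function(tp, value, bw = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$val)) {
    length(tp$val) <- 2L * n
    length(tp$bw) <- 2L * n
  }
  tp$val[[n]] <- value
  if (!is.null(bw)) tp$bw[[n]] <- bw
  tp$n <- n
  n
}

tp_val <- function(tp, id) {
  force(id)
  tp$val[[id]]
}

tp_acc <- function(tp, id, g) {
  cur <- tp$grad[[id]]
  tp$grad[[id]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

tp_backward <- function(tp, loss_id, seed_grad = 1) {
  tp$grad <- vector("list", tp$n)
  tp$grad[[loss_id]] <- seed_grad
  for (i in seq.int(loss_id, 1L)) {
    g <- tp$grad[[i]]
    if (!is.null(g) && !is.null(tp$bw[[i]])) tp$bw[[i]](g)
  }
  invisible(tp)
}

tp_grad <- function(tp, id) {
  force(id)
  tp$grad[[id]]
}

# ---- ops -------------------------------------------------------------------

tp_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$val[[a]]; B <- tp$val[[b]]
  tp_push(tp, A %*% B, function(g) {
    tp_acc(tp, a, tcrossprod(g, B))
    tp_acc(tp, b, crossprod(A, g))
  })
}

# X %*% W + bias (bias broadcast over rows); W and b may be parameter nodes
tp_linear <- function(tp, x, w, b = NULL) {
  force(x); force(w); force(b)
  X <- tp$val[[x]]; W <- tp$val[[w]]
  Y <- X %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, tp$val[[b]], "+")
  tp_push(tp, Y, function(g) {
    tp_acc(tp, x, tcrossprod(g, W))
    tp_acc(tp, w, crossprod(X, g))
    if (!is.null(b)) tp_acc(tp, b, colSums(g))
  })
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$val[[a]] + tp$val[[b]], function(g) {
    tp_acc(tp, a, g); tp_acc(tp, b, g)
  })
}

tp_scale <- function(tp, a, s) {
  force(a)
  tp_push(tp, tp$val[[a]] * s, function(g) tp_acc(tp, a, g * s))
}

tp_mul_const <- function(tp, a, m) {
  force(a)
  tp_push(tp, tp$val[[a]] * m, function(g) tp_acc(tp, a, g * m))
}

tp_relu <- function(tp, a) {
  force(a)
  X <- tp$val[[a]]
  pos <- X > 0
  tp_push(tp, X * pos, function(g) tp_acc(tp, a, g * pos))
}

tp_leaky_relu <- function(tp, a, slope = 0.01) {
  force(a)
  X <- tp$val[[a]]
  neg <- X < 0
  Y <- X
  Y[neg] <- slope * X[neg]
  tp_push(tp, Y, function(g) {
    g[neg] <- slope * g[neg]
    tp_acc(tp, a, g)
  })
}

tp_sigmoid <- function(tp, a) {
  force(a)
  S <- 1 / (1 + exp(-tp$val[[a]]))
  tp_push(tp, S, function(g) tp_acc(tp, a, g * S * (1 - S)))
}

tp_gather_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$val[[a]]
  tp_push(tp, A[idx, , drop = FALSE], function(g) {
    d <- matrix(0, nrow(A), ncol(A))
    rs <- rowsum(g, group = idx)
    d[as.integer(rownames(rs)), ] <- rs
    tp_acc(tp, a, d)
  })
}

# segment sum: Y[j, ] = sum of rows of A with group == j, j in 1..ngroups
tp_rowsum_by <- function(tp, a, group, ngroups) {
  force(a)
  A <- tp$val[[a]]
  Y <- matrix(0, ngroups, ncol(A))
  if (nrow(A) > 0L) {
    rs <- rowsum(A, group = group)
    Y[as.integer(rownames(rs)), ] <- rs
  }
  tp_push(tp, Y, function(g) {
    if (nrow(A) > 0L) tp_acc(tp, a, g[group, , drop = FALSE])
  })
}

tp_concat_rows <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp$val[[i]])
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, do.call(rbind, vals), function(g) {
    for (j in seq_along(ids))
      if (nr[j] > 0L)
        tp_acc(tp, ids[[j]], g[starts[j]:ends[j], , drop = FALSE])
  })
}

tp_concat_cols <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp$val[[i]])
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, do.call(cbind, vals), function(g) {
    for (j in seq_along(ids))
      tp_acc(tp, ids[[j]], g[, starts[j]:ends[j], drop = FALSE])
  })
}

tp_subset_rows <- function(tp, a, rows) {
  force(a)
  A <- tp$val[[a]]
  tp_push(tp, A[rows, , drop = FALSE], function(g) {
    d <- matrix(0, nrow(A), ncol(A))
    d[rows, ] <- g
    tp_acc(tp, a, d)
  })
}

# same-padded 1-D convolution over rows; W is (k * C_in) x C_out
.im2col <- function(X, k) {
  L <- nrow(X); C <- ncol(X); p <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, p, C), X, matrix(0, p, C))
  out <- matrix(0, L, k * C)
  for (j in seq_len(k))
    out[, ((j - 1L) * C + 1L):(j * C)] <- Xp[j:(j + L - 1L), , drop = FALSE]
  out
}

.fw_conv1d <- function(X, W, b, k) {
  cols <- .im2col(X, k)
  Y <- cols %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, cols = cols)
}

tp_conv1d <- function(tp, x, w, b, k) {
  force(x); force(w); force(b)
  X <- tp$val[[x]]; W <- tp$val[[w]]
  f <- .fw_conv1d(X, W, tp$val[[b]], k)
  L <- nrow(X); C <- ncol(X); p <- (k - 1L) %/% 2L
  tp_push(tp, f$Y, function(g) {
    tp_acc(tp, w, crossprod(f$cols, g))
    tp_acc(tp, b, colSums(g))
    dcols <- tcrossprod(g, W)
    dXp <- matrix(0, L + 2L * p, C)
    for (j in seq_len(k))
      dXp[j:(j + L - 1L), ] <- dXp[j:(j + L - 1L), ] +
        dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    tp_acc(tp, x, dXp[(p + 1L):(p + L), , drop = FALSE])
  })
}

# masked scaled-dot-product attention: Q, K, V nodes; masks logical vectors.
# Returns list(id = output node, A = attention matrix).
.fw_masked_softmax <- function(S, qmask, kmask) {
  if (all(kmask)) {
    mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
    E <- exp(S - mx)
    A <- E / rowSums(E)
  } else {
    A <- matrix(0, nrow(S), ncol(S))
    if (any(kmask)) {
      Sm <- S[, kmask, drop = FALSE]
      mx <- Sm[cbind(seq_len(nrow(Sm)), max.col(Sm, ties.method = "first"))]
      E <- exp(Sm - mx)
      A[, kmask] <- E / rowSums(E)
    }
  }
  if (!all(qmask)) A[!qmask, ] <- 0
  A
}

tp_attend <- function(tp, q, k, v, qmask, kmask, d_k) {
  force(q); force(k); force(v)
  Q <- tp$val[[q]]; K <- tp$val[[k]]; V <- tp$val[[v]]
  S <- tcrossprod(Q, K) / sqrt(d_k)
  A <- .fw_masked_softmax(S, qmask, kmask)
  H <- A %*% V
  id <- tp_push(tp, H, function(g) {
    dA <- tcrossprod(g, V)
    tp_acc(tp, v, crossprod(A, g))
    dS <- A * (dA - rowSums(dA * A))   # softmax Jacobian, rowwise
    dS <- dS / sqrt(d_k)
    tp_acc(tp, q, dS %*% K)
    tp_acc(tp, k, crossprod(dS, Q))
  })
  list(id = id, A = A)
}

# masked max-pool over rows -> 1 x d
tp_maxpool <- function(tp, a, mask) {
  force(a)
  X <- tp$val[[a]]
  rows <- which(mask)
  Xm <- X[rows, , drop = FALSE]
  arg <- rows[max.col(t(Xm), ties.method = "first")]
  z <- X[cbind(arg, seq_len(ncol(X)))]
  tp_push(tp, matrix(z, 1L), function(g) {
    d <- matrix(0, nrow(X), ncol(X))
    d[cbind(arg, seq_len(ncol(X)))] <- as.numeric(g)
    tp_acc(tp, a, d)
  })
}

tp_dropout <- function(tp, a, rate, training) {
  if (!training || rate <= 0) return(a)
  X <- tp$val[[a]]
  m <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  tp_mul_const(tp, a, m)
}

# one directed-message-passing aggregation step (messages only, no update)
.fw_dmpnn_message <- function(H, P, edges, rev_edge, message_fn) {
  E <- nrow(edges)
  if (E == 0L) return(H)
  src <- edges[, 1L]; tgt <- edges[, 2L]
  Tm <- if (message_fn == "mean") {
    (P[tgt, , drop = FALSE] + P[src, , drop = FALSE] + H) / 3
  } else {
    H
  }
  n <- nrow(P)
  S <- matrix(0, n, ncol(H))
  rs <- rowsum(Tm, group = tgt)
  S[as.integer(rownames(rs)), ] <- rs
  S[src, , drop = FALSE] - Tm[rev_edge, , drop = FALSE]
}

tp_dmpnn_message <- function(tp, h, p_node, edges, rev_edge, message_fn) {
  force(h); force(p_node)
  H <- tp$val[[h]]; P <- tp$val[[p_node]]
  E <- nrow(edges)
  M <- .fw_dmpnn_message(H, P, edges, rev_edge, message_fn)
  tp_push(tp, M, function(g) {
    if (E == 0L) { tp_acc(tp, h, g); return(invisible(NULL)) }
    src <- edges[, 1L]; tgt <- edges[, 2L]
    n <- nrow(P)
    # dS via src gather, minus reverse-edge term
    dS <- matrix(0, n, ncol(g))
    rs <- rowsum(g, group = src)
    dS[as.integer(rownames(rs)), ] <- rs
    dT <- dS[tgt, , drop = FALSE] - g[rev_edge, , drop = FALSE]
    if (message_fn == "mean") {
      dT3 <- dT / 3
      tp_acc(tp, h, dT3)
      dP <- matrix(0, n, ncol(P))
      rs1 <- rowsum(dT3, group = tgt)
      dP[as.integer(rownames(rs1)), ] <- dP[as.integer(rownames(rs1)), ] + rs1
      rs2 <- rowsum(dT3, group = src)
      dP[as.integer(rownames(rs2)), ] <- dP[as.integer(rownames(rs2)), ] + rs2
      tp_acc(tp, p_node, dP)
    } else {
      tp_acc(tp, h, dT)
    }
  })
}

# binary cross-entropy of a single probability node (1x1) against label t
tp_bce <- function(tp, p_id, t, eps = 1e-7) {
  force(p_id)
  p <- as.numeric(tp$val[[p_id]])
  pc <- min(max(p, eps), 1 - eps)
  loss <- -(t * log(pc) + (1 - t) * log(1 - pc))
  clipped <- (p < eps) || (p > 1 - eps)
  tp_push(tp, loss, function(g) {
    d <- if (clipped) 0 else g * (-(t / pc) + (1 - t) / (1 - pc))
    tp_acc(tp, p_id, matrix(d, 1L, 1L))
  })
}
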