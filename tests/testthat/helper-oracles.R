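# Independent reference implementations used as oracles. All deliberately
# written as scalar loops over definitions, sharing no code with the package.

# scaled-dot-product attention, one query/key pair at a time
oracle_attention <- function(Q, K, V, qmask, kmask, d_k) {
  Lq <- nrow(Q); Lk <- nrow(K)
  A <- matrix(0, Lq, Lk)
  H <- matrix(0, Lq, ncol(V))
  for (i in seq_len(Lq)) {
    if (!qmask[i]) next
    s <- rep(-Inf, Lk)
    for (j in seq_len(Lk))
      if (kmask[j]) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    m <- max(s[kmask])
    e <- ifelse(kmask, exp(s - m), 0)
    A[i, ] <- e / sum(e)
    for (j in seq_len(Lk)) H[i, ] <- H[i, ] + A[i, j] * V[j, ]
  }
  list(H = H, A = A)
}

# D-MPNN by doubly nested loops straight from the update definitions
oracle_dmpnn <- function(g, p) {
  E <- nrow(g$edges); d <- p$d
  H <- matrix(0, E, d)
  for (e in seq_len(E)) {
    v <- g$edges[e, 1]
    z <- c(g$atom_features[v, ], g$bond_features[e, ])
    H[e, ] <- pmax(0, as.numeric(z %*% p$W_b))
  }
  P <- g$atom_features %*% p$W_x
  for (t in seq_len(p$n_iter)) {
    M <- matrix(0, E, d)
    for (e in seq_len(E)) {
      v <- g$edges[e, 1]; w <- g$edges[e, 2]
      for (e2 in seq_len(E)) {
        if (g$edges[e2, 2] == v && g$edges[e2, 1] != w) {
          k <- g$edges[e2, 1]
          term <- if (p$message_fn == "mean") (P[v, ] + P[k, ] + H[e2, ]) / 3
                  else H[e2, ]
          M[e, ] <- M[e, ] + term
        }
      }
    }
    Hn <- matrix(0, E, d)
    for (e in seq_len(E))
      Hn[e, ] <- pmax(0, as.numeric(c(H[e, ], M[e, ]) %*% p$W_f) + p$b_f)
    H <- Hn
  }
  X <- matrix(0, g$n_atoms, d)
  for (v in seq_len(g$n_atoms)) {
    m <- rep(0, d)
    for (e in seq_len(E)) if (g$edges[e, 2] == v) m <- m + H[e, ]
    X[v, ] <- pmax(0, as.numeric(c(g$atom_features[v, ], m) %*% p$W_alpha))
  }
  X
}

# AUC by concordant-pair counting (ties count one half)
oracle_auc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos)
    for (j in neg)
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# AUPR by explicit threshold sweep over distinct scores
oracle_aupr <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp); rec <- tp / sum(labels == 1)
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

# random modality matrix with a suffix of masked (zeroed) positions
rand_modal <- function(L, d, n_masked = 0, modality = "") {
  mask <- c(rep(TRUE, L - n_masked), rep(FALSE, n_masked))
  new_modal_matrix(matrix(rnorm(L * d), L, d), mask, modality)
}

# apply an atom relabeling pi to a molecular_graph (row i of the new graph is
# atom perm[i] of the old one)
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, , drop = FALSE]
  g2$elements <- g$elements[perm]
  g2$aromatic <- g$aromatic[perm]
  g2$edges <- cbind(src = inv[g$edges[, 1]], tgt = inv[g$edges[, 2]])
  g2
}

small_molecule_pool <- function(max_atoms = 8L, n = 40L, seed = 11L) {
  smi <- gen_molecules(n, size_range = c(3L, max_atoms), seed = seed)
  smi[vapply(smi, function(s) smiles_to_graph(s)$n_atoms <= max_atoms, logical(1))]
}
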