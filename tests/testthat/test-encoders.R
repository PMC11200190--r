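test_that("embedding lookup is a deterministic row gather with zero padding", {
  set.seed(1)
  tab <- new_embedding_table(23L, 4L)
  tv <- new_token_vector(c(5L, 5L, 0L), 2L)
  X <- embed_tokens(tv, tab)
  expect_equal(X$values[1, ], X$values[2, ])
  expect_equal(X$values[3, ], rep(0, 4))

  # identity table: id i maps to unit vector e_i
  tab$weights <- diag(23)[, 1:23]
  X <- embed_tokens(new_token_vector(c(2L, 1L), 2L), tab)
  expect_equal(X$values[1, ], as.numeric(seq_len(23) == 3))
  expect_equal(X$values[2, ], as.numeric(seq_len(23) == 2))

  expect_error(embed_tokens(new_token_vector(c(40L), 1L), new_embedding_table(23L, 4L)),
               class = "dtifuse_index_error")
})

test_that("cnn block preserves length, applies identity kernels exactly, and re-zeroes masks", {
  d <- 6L
  # single size-1 identity layer reproduces nonnegative input
  p <- cnn_block_params(d, kernel_sizes = 1L)
  p$layers[[1]]$W <- diag(d)
  X <- rand_modal(5L, d)
  X$values <- abs(X$values)
  expect_equal(cnn_block(X, p)$values, X$values)

  # zero input stays zero through randomly initialized layers with zero bias
  set.seed(2)
  p3 <- cnn_block_params(8L)
  Z <- new_modal_matrix(matrix(0, 7, 8), rep(TRUE, 7))
  expect_true(all(cnn_block(Z, p3)$values == 0))

  # same-padding: 7 x 8 in, 7 x d out after 3 layers; masked rows exactly zero
  Xm <- rand_modal(7L, 8L, n_masked = 3L)
  out <- cnn_block(Xm, p3)
  expect_identical(dim(out$values), c(7L, 8L))
  expect_true(all(out$values[!Xm$mask, ] == 0))

  expect_error(cnn_block(rand_modal(4L, 5L), p3), class = "dtifuse_shape_error")
})

test_that("edge initialization is ReLU(W_b [x_v; e_vw]) and empty graphs give empty states", {
  set.seed(3)
  p <- dmpnn_params(4L)
  g <- smiles_to_graph("CCO")
  h0 <- dmpnn_init_edges(g, p)
  expect_identical(dim(h0), c(4L, 4L))
  e1 <- c(g$atom_features[g$edges[1, 1], ], g$bond_features[1, ])
  expect_equal(h0[1, ], pmax(0, as.numeric(e1 %*% p$W_b)))

  p0 <- p; p0$W_b[] <- 0
  expect_true(all(dmpnn_init_edges(g, p0) == 0))
  expect_identical(dim(dmpnn_init_edges(smiles_to_graph("C"), p)), c(0L, 4L))
})

test_that("messages exclude the reverse edge: 2-atom graphs pass zero messages", {
  set.seed(4)
  p <- dmpnn_params(5L)
  g <- smiles_to_graph("CO")     # one bond, two directed edges
  h0 <- dmpnn_init_edges(g, p)
  m <- dtifuse:::.fw_dmpnn_message(h0, g$atom_features %*% p$W_x,
                                   g$edges, g$rev_edge, p$message_fn)
  expect_true(all(abs(m) < 1e-12))
  # hence the update reduces to ReLU(W_f [h0; 0])
  p1 <- p; p1$n_iter <- 1L
  h1 <- dmpnn_iterate(g, h0, p1)
  expect_equal(h1, pmax(sweep(cbind(h0, m) %*% p$W_f, 2, p$b_f, "+"), 0))
})

test_that("on a 3-atom path the (B->C) message aggregates only edge (A->B)", {
  set.seed(5)
  p <- dmpnn_params(4L)
  g <- smiles_to_graph("CCO")    # path C1-C2-O3
  h0 <- dmpnn_init_edges(g, p)
  P <- g$atom_features %*% p$W_x
  m <- dtifuse:::.fw_dmpnn_message(h0, P, g$edges, g$rev_edge, "mean")
  e_bc <- which(g$edges[, 1] == 2L & g$edges[, 2] == 3L)
  e_ab <- which(g$edges[, 1] == 1L & g$edges[, 2] == 2L)
  expect_equal(m[e_bc, ], (P[2, ] + P[1, ] + h0[e_ab, ]) / 3)
})

test_that("vectorized D-MPNN matches the nested-loop oracle on small molecules", {
  set.seed(6)
  pool <- small_molecule_pool(max_atoms = 8L)
  expect_gt(length(pool), 5L)
  for (fn in c("mean", "edge_hidden_sum")) {
    p <- dmpnn_params(6L, n_iter = 2L, message_fn = fn)
    for (s in pool) {
      g <- smiles_to_graph(s)
      X <- dmpnn_encode(g, p)
      expect_identical(nrow(X$values), g$n_atoms)
      expect_lt(max(abs(X$values - oracle_dmpnn(g, p))), 1e-6)
    }
  }
})

test_that("node features are permutation-equivariant", {
  set.seed(7)
  p <- dmpnn_params(6L)
  smi <- gen_molecules(25, seed = 9)
  for (s in smi) {
    g <- smiles_to_graph(s)
    perm <- sample(g$n_atoms)
    g2 <- permute_graph(g, perm)
    X <- dmpnn_encode(g, p)$values
    X2 <- dmpnn_encode(g2, p)$values
    expect_lt(max(abs(X2 - X[perm, , drop = FALSE])), 1e-6)
  }
})

test_that("outputs stay finite across message-passing depths 1..5", {
  set.seed(8)
  smi <- gen_molecules(10, seed = 10)
  for (T in 1:5) {
    p <- dmpnn_params(6L, n_iter = T)
    for (s in smi) expect_true(all(is.finite(dmpnn_encode(smiles_to_graph(s), p)$values)))
  }
  expect_error(dmpnn_params(6L, n_iter = 0L), class = "dtifuse_config_error")
})
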