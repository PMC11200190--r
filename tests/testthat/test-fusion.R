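test_that("degenerate attention cases behave as the softmax definition demands", {
  set.seed(10)
  d <- 4L
  p <- attention_params(d)

  # single token: A = [[1]], H = that token's value vector
  X1 <- rand_modal(1L, d)
  out <- masked_self_attention(X1, p)
  expect_equal(out$A, matrix(1, 1, 1))
  expect_equal(out$H[1, ], as.numeric(X1$values %*% p$W_V + p$b_V))

  # two identical tokens -> identical keys -> uniform rows
  X2 <- new_modal_matrix(matrix(rnorm(d), 2, d, byrow = TRUE), c(TRUE, TRUE))
  out <- masked_self_attention(X2, p)
  expect_equal(out$A, matrix(0.5, 2, 2))

  # one key forces every cross-attention row onto the single value vector
  Xq <- rand_modal(2L, d); Xk <- rand_modal(1L, d)
  out <- cross_attention(Xq, Xk, p)
  v <- as.numeric(Xk$values %*% p$W_V + p$b_V)
  expect_equal(out$H[1, ], v)
  expect_equal(out$H[2, ], v)

  expect_error(masked_self_attention(new_modal_matrix(matrix(0, 2, d),
                                                      c(FALSE, FALSE)), p),
               class = "dtifuse_invalid_input")
})

test_that("attention matches the nested-loop oracle over random shapes and masks", {
  set.seed(11)
  for (rep in 1:50) {
    d <- sample(2:8, 1)
    Lq <- sample(1:7, 1); Lk <- sample(1:7, 1)
    p <- attention_params(d)
    Xq <- rand_modal(Lq, d, n_masked = sample(0:(Lq - 1), 1))
    Xk <- rand_modal(Lk, d, n_masked = sample(0:(Lk - 1), 1))

    qkv_self <- list(Q = sweep(Xq$values %*% p$W_Q, 2, p$b_Q, "+"),
                     K = sweep(Xq$values %*% p$W_K, 2, p$b_K, "+"),
                     V = sweep(Xq$values %*% p$W_V, 2, p$b_V, "+"))
    ref <- oracle_attention(qkv_self$Q, qkv_self$K, qkv_self$V,
                            Xq$mask, Xq$mask, p$d_k)
    out <- masked_self_attention(Xq, p)
    expect_lt(max(abs(out$H - ref$H)), 1e-6)
    expect_lt(max(abs(out$A - ref$A)), 1e-6)

    qkv_x <- list(Q = sweep(Xq$values %*% p$W_Q, 2, p$b_Q, "+"),
                  K = sweep(Xk$values %*% p$W_K, 2, p$b_K, "+"),
                  V = sweep(Xk$values %*% p$W_V, 2, p$b_V, "+"))
    refx <- oracle_attention(qkv_x$Q, qkv_x$K, qkv_x$V, Xq$mask, Xk$mask, p$d_k)
    outx <- cross_attention(Xq, Xk, p)
    expect_lt(max(abs(outx$H - refx$H)), 1e-6)

    # joint-stream level: equals plain self-attention on the stacked stream
    lv <- hmsa_level(Xq, Xk, p)
    Xc <- new_modal_matrix(rbind(Xq$values, Xk$values), c(Xq$mask, Xk$mask))
    qkv_c <- list(Q = sweep(Xc$values %*% p$W_Q, 2, p$b_Q, "+"),
                  K = sweep(Xc$values %*% p$W_K, 2, p$b_K, "+"),
                  V = sweep(Xc$values %*% p$W_V, 2, p$b_V, "+"))
    refc <- oracle_attention(qkv_c$Q, qkv_c$K, qkv_c$V, Xc$mask, Xc$mask, p$d_k)
    expect_lt(max(abs(rbind(lv$Ha, lv$Hb) - refc$H)), 1e-6)
  }
})

test_that("joint-stream attention equals the hand-assembled four-block form", {
  set.seed(12)
  for (rep in 1:10) {
    d <- 5L
    p <- attention_params(d)
    Xa <- rand_modal(sample(2:5, 1), d)
    Xb <- rand_modal(sample(2:5, 1), d)
    La <- nrow(Xa$values)
    Qa <- sweep(Xa$values %*% p$W_Q, 2, p$b_Q, "+")
    Qb <- sweep(Xb$values %*% p$W_Q, 2, p$b_Q, "+")
    Ka <- sweep(Xa$values %*% p$W_K, 2, p$b_K, "+")
    Kb <- sweep(Xb$values %*% p$W_K, 2, p$b_K, "+")
    Va <- sweep(Xa$values %*% p$W_V, 2, p$b_V, "+")
    Vb <- sweep(Xb$values %*% p$W_V, 2, p$b_V, "+")
    # the four intra/inter blocks, then one joint row-softmax
    S <- rbind(cbind(Qa %*% t(Ka), Qa %*% t(Kb)),
               cbind(Qb %*% t(Ka), Qb %*% t(Kb))) / sqrt(p$d_k)
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    H <- A %*% rbind(Va, Vb)
    lv <- hmsa_level(Xa, Xb, p)
    expect_lt(max(abs(lv$Ha - H[seq_len(La), ])), 1e-6)
    expect_lt(max(abs(lv$Hb - H[-seq_len(La), ])), 1e-6)
    # inter-modal mass is strictly positive for generic inputs
    expect_gt(min(rowSums(lv$A[seq_len(La), -seq_len(La), drop = FALSE])), 0)
  }
})

test_that("an empty second stream reduces the joint level to plain self-attention", {
  set.seed(13)
  d <- 4L
  p <- attention_params(d)
  Xa <- rand_modal(3L, d)
  Xb <- new_modal_matrix(matrix(0, 0, d), logical(0))
  lv <- hmsa_level(Xa, Xb, p)
  expect_equal(lv$Ha, masked_self_attention(Xa, p)$H)
  expect_identical(nrow(lv$Hb), 0L)
})

test_that("cross-attention output is confined to the value row span; joint attention is not", {
  set.seed(14)
  d <- 6L
  in_span <- function(H, V) {
    # residual of least-squares projection of each output row onto rows of V
    proj <- t(qr.fitted(qr(t(V)), t(H)))
    max(abs(H - proj))
  }
  n_joint_outside <- 0L
  for (rep in 1:20) {
    p <- attention_params(d)
    Xq <- rand_modal(4L, d); Xk <- rand_modal(3L, d)
    Vk <- sweep(Xk$values %*% p$W_V, 2, p$b_V, "+")
    H <- cross_attention(Xq, Xk, p)$H
    expect_lt(in_span(H, Vk), 1e-8)
    lv <- hmsa_level(Xq, Xk, p)
    if (in_span(lv$Ha, Vk) > 1e-4) n_joint_outside <- n_joint_outside + 1L
  }
  expect_gte(n_joint_outside, 19L)
})

test_that("every attention matrix is row-stochastic over unmasked keys with exact zeros at masked ones", {
  set.seed(15)
  for (rep in 1:20) {
    d <- 4L
    p <- attention_params(d)
    L <- sample(3:8, 1)
    X <- rand_modal(L, d, n_masked = sample(0:(L - 2), 1))
    A <- masked_self_attention(X, p)$A
    expect_equal(rowSums(A)[X$mask], rep(1, sum(X$mask)), tolerance = 1e-6)
    if (any(!X$mask)) {
      expect_true(all(A[, !X$mask] == 0))
      expect_true(all(A[!X$mask, ] == 0))
    }
  }
})

test_that("full fusion respects shapes, residual isolation and graph-row permutation", {
  set.seed(16)
  d <- 5L
  mk <- function() list(p1d = attention_params(d), p1p = attention_params(d),
                        p2 = attention_params(d))
  ps <- mk()
  Xs <- rand_modal(4L, d, modality = "smiles")
  Xg <- rand_modal(3L, d, modality = "graph")
  Xq <- rand_modal(6L, d, modality = "seq")
  Xm <- rand_modal(5L, d, modality = "mer")
  fz <- hmsa_fuse(Xs, Xg, Xq, Xm, ps$p1d, ps$p1p, ps$p2)
  expect_identical(dim(fz$bundle$D_graph), dim(Xg$values))
  expect_identical(dim(fz$bundle$D_mer), dim(Xm$values))
  for (z in fz$pooled) expect_length(z, d)

  # with all value projections zeroed the attention contributes nothing:
  # pooled features reduce to max-pooling the encoder outputs
  ps0 <- mk()
  for (nm in names(ps0)) { ps0[[nm]]$W_V[] <- 0; ps0[[nm]]$b_V[] <- 0 }
  fz0 <- hmsa_fuse(Xs, Xg, Xq, Xm, ps0$p1d, ps0$p1p, ps0$p2)
  expect_equal(fz0$pooled$Z_smiles, apply(Xs$values, 2, max))
  expect_equal(fz0$pooled$Z_graph, apply(Xg$values, 2, max))

  # permuting atom rows leaves all four pooled vectors unchanged
  perm <- sample(nrow(Xg$values))
  Xg2 <- new_modal_matrix(Xg$values[perm, ], Xg$mask[perm], "graph")
  fz2 <- hmsa_fuse(Xs, Xg2, Xq, Xm, ps$p1d, ps$p1p, ps$p2)
  for (nm in names(fz$pooled))
    expect_lt(max(abs(fz$pooled[[nm]] - fz2$pooled[[nm]])), 1e-6)

  # determinism: identical inputs give bit-identical outputs
  fz3 <- hmsa_fuse(Xs, Xg, Xq, Xm, ps$p1d, ps$p1p, ps$p2)
  expect_identical(fz$pooled, fz3$pooled)
})

test_that("attention matrices export to long-format TSV", {
  set.seed(17)
  out <- masked_self_attention(rand_modal(3L, 4L), attention_params(4L))
  path <- tempfile(fileext = ".tsv")
  dt <- write_attention(out, path)
  expect_true(file.exists(path))
  expect_named(dt, c("query", "key", "weight"))
  expect_equal(sum(dt$weight), 3, tolerance = 1e-6)
})
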