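# Modality encoders: embedding + convolutional blocks for the three token
# streams, and a readout-free directed message-passing network (D-MPNN) for
# molecular graphs. These are the forward-only public operations; the training
# path drives the same math through the gradient tape (see autodiff.R), and the
# two are held equal by tests.

#' Construct a modality feature matrix
#'
#' @param values L x d numeric matrix; rows at masked positions must be zero.
#' @param mask Logical vector of length L (TRUE = real token/atom).
#' @param modality One of `"smiles"`, `"graph"`, `"seq"`, `"mer"`, or `""`.
#' @return A `modal_matrix` object.
#' @export
new_modal_matrix <- function(values, mask, modality = "") {
  values <- as.matrix(values)
  if (nrow(values) != length(mask))
    stop_shape("mask length must equal the number of rows")
  values[!mask, ] <- 0
  structure(list(values = values, mask = as.logical(mask), modality = modality),
            class = "modal_matrix")
}

#' @export
print.modal_matrix <- function(x, ...) {
  cat(sprintf("<modal_matrix:%s> %d x %d (%d unmasked)\n",
              x$modality, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)

#' Create an embedding table
#'
#' Row 1 is the padding id 0 and is pinned to zero; it receives no gradient
#' updates during training.
#'
#' @param vocab_size Vocabulary size including the padding id (e.g. 23 for
#'   residues: pad + 22 symbols).
#' @param dim Embedding dimension d.
#' @return An `embedding_table` with fields `vocab_size`, `dim`, `weights`.
#' @export
new_embedding_table <- function(vocab_size, dim) {
  W <- matrix(stats::rnorm(vocab_size * dim, sd = 0.1), vocab_size, dim)
  W[1L, ] <- 0
  structure(list(vocab_size = as.integer(vocab_size), dim = as.integer(dim),
                 weights = W), class = "embedding_table")
}

#' Embed a token vector
#'
#' Row i of the output is the embedding of token id `ids[i]`; padded positions
#' map through the pinned zero row.
#'
#' @param tokens A `token_vector`.
#' @param table An `embedding_table`.
#' @return A `modal_matrix` of shape `length(ids) x dim`.
#' @export
embed_tokens <- function(tokens, table) {
  ids <- tokens$ids
  if (max(ids) + 1L > table$vocab_size)
    stop(errorCondition(
      sprintf("token id %d exceeds vocabulary size %d", max(ids), table$vocab_size),
      class = c("dtifuse_index_error", "dtifuse_error")))
  new_modal_matrix(table$weights[ids + 1L, , drop = FALSE], tokens$mask)
}

#' Parameters for a convolutional encoder block
#'
#' A stack of same-padded 1-D convolutions with rectifier activations; the
#' spatial length is preserved so token positions survive into fusion.
#'
#' @param d_in Input channel count (embedding dimension).
#' @param kernel_sizes Odd kernel sizes, one per layer (default 3, 5, 7).
#' @param channels Output channels per layer; the last must equal the model
#'   width d (default `d_in` throughout).
#' @return A `cnn_block_params` object with one `(k * C_in) x C_out` weight
#'   matrix and bias per layer.
#' @export
cnn_block_params <- function(d_in, kernel_sizes = c(3L, 5L, 7L), channels = NULL) {
  if (is.null(channels)) channels <- rep(d_in, length(kernel_sizes))
  if (length(channels) != length(kernel_sizes))
    stop_invalid("`channels` and `kernel_sizes` must have equal length")
  if (any(kernel_sizes %% 2L == 0L))
    stop_invalid("kernel sizes must be odd (same-padding)")
  cin <- d_in
  layers <- vector("list", length(kernel_sizes))
  for (i in seq_along(kernel_sizes)) {
    k <- kernel_sizes[i]; cout <- channels[i]
    layers[[i]] <- list(W = .he(k * cin, cout), b = numeric(cout), k = k)
    cin <- cout
  }
  structure(list(layers = layers, d_in = d_in, d_out = cin),
            class = "cnn_block_params")
}

#' Apply a convolutional encoder block
#'
#' Each layer is a same-padded 1-D convolution followed by ReLU; masked
#' positions are re-zeroed after every layer so padding never leaks through
#' the receptive field.
#'
#' @param X A `modal_matrix` with `d_in` channels.
#' @param params A `cnn_block_params`.
#' @return A `modal_matrix` with the same number of rows and `d_out` channels.
#' @export
cnn_block <- function(X, params) {
  V <- X$values
  if (ncol(V) != params$d_in)
    stop_shape(sprintf("input has %d channels, block expects %d",
                       ncol(V), params$d_in))
  for (ly in params$layers) {
    V <- .fw_conv1d(V, ly$W, ly$b, ly$k)$Y
    V[V < 0] <- 0
    V[!X$mask, ] <- 0
  }
  new_modal_matrix(V, X$mask, X$modality)
}

#' Parameters for the directed message-passing network
#'
#' Hidden states live on directed bonds. `W_b` initializes edge states from
#' concatenated atom and bond features; `W_f` (with bias, a fully connected
#' layer shared across iterations) updates them; `W_x` projects raw atom
#' features into the hidden space for the message average; `W_alpha` produces
#' node-level outputs. No readout is applied: atoms remain tokens.
#'
#' @param d Hidden dimension.
#' @param n_iter Message-passing depth T (default 2).
#' @param message_fn `"mean"` — elementwise mean of the projected source atom,
#'   projected neighbor atom and incoming edge state — or `"edge_hidden_sum"`,
#'   the classical convention where the message is the sum of incoming edge
#'   states alone.
#' @return A `dmpnn_params` object.
#' @export
dmpnn_params <- function(d, n_iter = 2L, message_fn = c("mean", "edge_hidden_sum")) {
  message_fn <- match.arg(message_fn)
  if (n_iter < 1L)
    stop(errorCondition("`n_iter` (T) must be >= 1",
                        class = c("dtifuse_config_error", "dtifuse_error")))
  fa <- atom_feature_dim(); fb <- bond_feature_dim()
  structure(list(
    W_b = .he(fa + fb, d),
    W_x = .he(fa, d),
    W_f = .he(2L * d, d),
    b_f = numeric(d),
    W_alpha = .he(fa + d, d),
    d = as.integer(d), n_iter = as.integer(n_iter), message_fn = message_fn),
    class = "dmpnn_params")
}

#' Initialize directed-edge hidden states
#'
#' `h0_vw = ReLU(W_b [x_v ; e_vw])` for every directed edge (v -> w).
#'
#' @param g A `molecular_graph`.
#' @param p A `dmpnn_params`.
#' @return An `E x d` matrix of edge hidden states (E = 2 x bonds).
#' @export
dmpnn_init_edges <- function(g, p) {
  E <- nrow(g$edges)
  if (E == 0L) return(matrix(0, 0L, p$d))
  Z <- cbind(g$atom_features[g$edges[, 1L], , drop = FALSE], g$bond_features)
  if (ncol(Z) != nrow(p$W_b)) stop_shape("atom/bond feature width does not match W_b")
  H <- Z %*% p$W_b
  H[H < 0] <- 0
  H
}

#' Run T directed message-passing iterations
#'
#' At each step the message for edge (v -> w) aggregates over incoming edges
#' (k -> v) with k != w — the reverse edge is excluded, preventing immediate
#' back-flow — and the edge state updates as
#' `h^{t+1} = ReLU(W_f [h^t ; m^{t+1}] + b_f)`. An empty neighbor set yields a
#' zero message.
#'
#' @param g A `molecular_graph`.
#' @param h0 Initial edge states from [dmpnn_init_edges()].
#' @param p A `dmpnn_params`.
#' @return The edge hidden states after `p$n_iter` iterations.
#' @export
dmpnn_iterate <- function(g, h0, p) {
  if (p$n_iter < 1L)
    stop(errorCondition("T must be >= 1",
                        class = c("dtifuse_config_error", "dtifuse_error")))
  H <- h0
  if (nrow(g$edges) == 0L) return(H)
  P <- g$atom_features %*% p$W_x
  for (t in seq_len(p$n_iter)) {
    M <- .fw_dmpnn_message(H, P, g$edges, g$rev_edge, p$message_fn)
    H <- sweep(cbind(H, M) %*% p$W_f, 2L, p$b_f, "+")
    H[H < 0] <- 0
  }
  H
}

#' Node-level graph features (no readout)
#'
#' Aggregates final edge states into per-atom messages
#' `m_v = sum_{k in N(v)} h_kv` and outputs
#' `h_v = ReLU(W_alpha [x_v ; m_v])`. No pooling is applied: the result is an
#' `n_atoms x d` token matrix that enters multimodal fusion alongside the
#' sequence streams.
#'
#' @param g A `molecular_graph`.
#' @param hT Edge states from [dmpnn_iterate()].
#' @param p A `dmpnn_params`.
#' @return A `modal_matrix` (modality `"graph"`) with one row per atom.
#' @export
dmpnn_node_features <- function(g, hT, p) {
  n <- g$n_atoms
  Msum <- matrix(0, n, p$d)
  if (nrow(g$edges) > 0L) {
    rs <- rowsum(hT, group = g$edges[, 2L])
    Msum[as.integer(rownames(rs)), ] <- rs
  }
  H <- cbind(g$atom_features, Msum) %*% p$W_alpha
  H[H < 0] <- 0
  new_modal_matrix(H, rep(TRUE, n), "graph")
}

#' Full graph encoder
#'
#' Convenience wrapper: init, iterate, node features.
#'
#' @inheritParams dmpnn_node_features
#' @return A `modal_matrix` (modality `"graph"`).
#' @export
dmpnn_encode <- function(g, p) {
  dmpnn_node_features(g, dmpnn_iterate(g, dmpnn_init_edges(g, p), p), p)
}
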