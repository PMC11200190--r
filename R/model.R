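# End-to-end predictor: four modality encoders -> hierarchical multimodal
# self-attention -> four-layer classifier -> interaction probability. Model
# parameters live in one flat named list so the optimizer and the checkpoint
# format stay trivial; structured views are materialized on demand for the
# public per-module operations.

#' Model / training configuration
#'
#' All tunables in one flat list. Defaults follow the method's declared
#' settings: k = 2 protein k-mers, D-MPNN depth T = 2, single-head attention
#' with `d_att = d`, 150 epochs and batch size 50; classifier hidden widths
#' shrink automatically for small desk-scale models (d <= 32).
#'
#' @param d Shared model width (embedding/attention dimension, default 64).
#' @param k Protein k-mer length (1, 2 or 3; default 2).
#' @param n_mpnn_iter D-MPNN message-passing depth T (default 2).
#' @param message_fn D-MPNN message aggregation, `"mean"` or
#'   `"edge_hidden_sum"` (see [dmpnn_params()]).
#' @param n_heads Attention heads (default 1).
#' @param L_smiles,L_protein Maximum SMILES / protein token lengths (prefix
#'   truncation beyond them); the k-mer cap is `L_protein - k + 1`.
#' @param kernel_sizes CNN kernel sizes per layer (default 3, 5, 7).
#' @param hidden Classifier hidden widths h1..h3; `NULL` picks
#'   (1024, 512, 256), scaled to (256, 128, 64) when `d <= 32`.
#' @param dropout Dropout rate after classifier layers 1-3 (default 0.1).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param fusion_mode `"hmsa"` (default), `"concat"` or `"cross_attention"` —
#'   the ablation grid.
#' @param epochs,batch_size Training-loop settings (defaults 150 and 50).
#' @param lr Adam learning rate (default 1e-4).
#' @param threshold Decision threshold for accuracy/precision/recall.
#' @param label_smooth_eps Probability clipping epsilon in the loss.
#' @param seed Seed used for parameter initialization and batch shuffling.
#' @param ... Further overrides stored verbatim.
#' @return A `dti_config` list.
#' @export
dti_config <- function(d = 64L, k = 2L, n_mpnn_iter = 2L,
                       message_fn = "mean", n_heads = 1L,
                       L_smiles = 150L, L_protein = 1000L,
                       kernel_sizes = c(3L, 5L, 7L), hidden = NULL,
                       dropout = 0.1, leaky_slope = 0.01,
                       fusion_mode = c("hmsa", "concat", "cross_attention"),
                       epochs = 150L, batch_size = 50L, lr = 1e-4,
                       threshold = 0.5, label_smooth_eps = 1e-7,
                       seed = 1L, ...) {
  fusion_mode <- match.arg(fusion_mode)
  if (!k %in% 1:3) stop_invalid("`k` must be 1, 2 or 3")
  if (epochs < 1L || batch_size < 1L)
    stop_invalid("`epochs` and `batch_size` must be >= 1")
  if (is.null(hidden)) hidden <- if (d <= 32L) c(256L, 128L, 64L) else c(1024L, 512L, 256L)
  structure(list(d = as.integer(d), k = as.integer(k),
                 n_mpnn_iter = as.integer(n_mpnn_iter),
                 message_fn = message_fn, n_heads = as.integer(n_heads),
                 L_smiles = as.integer(L_smiles), L_protein = as.integer(L_protein),
                 kernel_sizes = as.integer(kernel_sizes), hidden = as.integer(hidden),
                 dropout = dropout, leaky_slope = leaky_slope,
                 fusion_mode = fusion_mode, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 threshold = threshold, label_smooth_eps = label_smooth_eps,
                 seed = as.integer(seed), ...),
            class = "dti_config")
}

#' Initialize a model
#'
#' Draws all parameters (embedding tables with pinned zero padding rows, CNN
#' kernels, D-MPNN matrices, three attention modules, classifier) from the
#' configuration seed.
#'
#' @param config A [dti_config()].
#' @return A `dti_model`: list with `params` (flat named list of matrices /
#'   bias vectors) and `config`.
#' @export
dti_model <- function(config = dti_config()) {
  d <- config$d
  fa <- atom_feature_dim(); fb <- bond_feature_dim()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  emb <- function(vocab) {
    W <- matrix(stats::rnorm((vocab + 1L) * d, sd = 0.1), vocab + 1L, d)
    W[1L, ] <- 0  # padding id 0
    W
  }
  p <- list(
    emb.seq = emb(22L),
    emb.mer = emb(as.integer(kmer_vocab_size(config$k))),
    emb.smiles = emb(64L))
  for (stream in c("seq", "mer", "smiles")) {
    cin <- d
    for (i in seq_along(config$kernel_sizes)) {
      kk <- config$kernel_sizes[i]
      p[[sprintf("cnn.%s.W%d", stream, i)]] <- .he(kk * cin, d)
      p[[sprintf("cnn.%s.b%d", stream, i)]] <- numeric(d)
      cin <- d
    }
  }
  p$dmpnn.W_b <- .he(fa + fb, d)
  p$dmpnn.W_x <- .he(fa, d)
  p$dmpnn.W_f <- .he(2L * d, d)
  p$dmpnn.b_f <- numeric(d)
  p$dmpnn.W_alpha <- .he(fa + d, d)
  for (att in c("l1d", "l1p", "l2")) {
    for (m in c("Q", "K", "V")) {
      p[[sprintf("attn.%s.W_%s", att, m)]] <- .glorot(d, d)
      p[[sprintf("attn.%s.b_%s", att, m)]] <- numeric(d)
    }
  }
  widths <- c(4L * d, config$hidden, 1L)
  for (i in 1:4) {
    p[[sprintf("clf.W%d", i)]] <- .he(widths[i], widths[i + 1L])
    p[[sprintf("clf.b%d", i)]] <- numeric(widths[i + 1L])
  }
  structure(list(params = p, config = config), class = "dti_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.dti_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<dti_model> d=%d k=%d T=%d fusion=%s (%s parameters)\n",
              x$config$d, x$config$k, x$config$n_mpnn_iter,
              x$config$fusion_mode, format(np, big.mark = ",")))
  invisible(x)
}

#' Extract a structured parameter view from a model
#'
#' Bridges the flat trained parameter list and the per-module public
#' operations ([cnn_block()], [dmpnn_iterate()], [masked_self_attention()],
#' ...), which take structured parameter objects.
#'
#' @param model A `dti_model`.
#' @param component One of `"cnn_seq"`, `"cnn_mer"`, `"cnn_smiles"`,
#'   `"dmpnn"`, `"attn_level1_drug"`, `"attn_level1_protein"`,
#'   `"attn_level2"`, `"embedding_seq"`, `"embedding_mer"`,
#'   `"embedding_smiles"`, `"classifier"`.
#' @return The corresponding parameter object.
#' @export
model_params <- function(model, component) {
  p <- model$params; cfg <- model$config
  if (grepl("^cnn_", component)) {
    stream <- sub("^cnn_", "", component)
    layers <- lapply(seq_along(cfg$kernel_sizes), function(i) {
      list(W = p[[sprintf("cnn.%s.W%d", stream, i)]],
           b = p[[sprintf("cnn.%s.b%d", stream, i)]],
           k = cfg$kernel_sizes[i])
    })
    return(structure(list(layers = layers, d_in = cfg$d, d_out = cfg$d),
                     class = "cnn_block_params"))
  }
  if (component == "dmpnn")
    return(structure(list(W_b = p$dmpnn.W_b, W_x = p$dmpnn.W_x,
                          W_f = p$dmpnn.W_f, b_f = p$dmpnn.b_f,
                          W_alpha = p$dmpnn.W_alpha, d = cfg$d,
                          n_iter = cfg$n_mpnn_iter, message_fn = cfg$message_fn),
                     class = "dmpnn_params"))
  if (grepl("^attn_", component)) {
    key <- c(attn_level1_drug = "l1d", attn_level1_protein = "l1p",
             attn_level2 = "l2")[[component]]
    return(structure(list(
      W_Q = p[[sprintf("attn.%s.W_Q", key)]], b_Q = p[[sprintf("attn.%s.b_Q", key)]],
      W_K = p[[sprintf("attn.%s.W_K", key)]], b_K = p[[sprintf("attn.%s.b_K", key)]],
      W_V = p[[sprintf("attn.%s.W_V", key)]], b_V = p[[sprintf("attn.%s.b_V", key)]],
      d = cfg$d, d_att = cfg$d, d_k = cfg$d, n_heads = cfg$n_heads),
      class = "attention_params"))
  }
  if (grepl("^embedding_", component)) {
    W <- p[[sub("embedding_", "emb.", component)]]
    return(structure(list(vocab_size = nrow(W), dim = ncol(W), weights = W),
                     class = "embedding_table"))
  }
  if (component == "classifier")
    return(structure(list(W1 = p$clf.W1, b1 = p$clf.b1, W2 = p$clf.W2, b2 = p$clf.b2,
                          W3 = p$clf.W3, b3 = p$clf.b3, W4 = p$clf.W4, b4 = p$clf.b4,
                          dropout = cfg$dropout, leaky_slope = cfg$leaky_slope),
                     class = "classifier_params"))
  stop_invalid(sprintf("unknown component '%s'", component))
}

# ---- featurization ---------------------------------------------------------

#' Featurize one drug-protein record
#'
#' Produces the four modality inputs with tight lengths (no padding beyond
#' the true, possibly truncated, length): SMILES tokens, molecular graph,
#' protein sequence tokens and k-mer tokens.
#'
#' @param smiles SMILES string.
#' @param sequence Protein residue string.
#' @param config A [dti_config()].
#' @return List with `tok_smiles`, `tok_seq`, `tok_mer` (token vectors) and
#'   `graph` (a `molecular_graph`).
#' @export
featurize_record <- function(smiles, sequence, config = dti_config()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop_invalid("`sequence` must be a non-empty residue string")
  g <- smiles_to_graph(smiles)
  ns <- min(nchar(smiles), config$L_smiles)
  np <- min(nchar(sequence), config$L_protein)
  nm <- min(nchar(sequence) - config$k + 1L, config$L_protein - config$k + 1L)
  list(tok_smiles = tokenize_smiles(smiles, L_max = ns),
       tok_seq = encode_protein_sequence(sequence, L_max = np),
       tok_mer = make_kmer_tokens(sequence, k = config$k, L_max = nm),
       graph = g)
}

# ---- tape forward ----------------------------------------------------------

# Register every parameter as a tape node once; returns name -> node id map.
.tp_params <- function(tp, model) {
  ids <- vapply(names(model$params),
                function(nm) tp_push(tp, model$params[[nm]]), integer(1))
  names(ids) <- names(model$params)
  ids
}

.tp_token_encoder <- function(tp, pid, stream, tok, cfg) {
  x <- tp_gather_rows(tp, pid[[paste0("emb.", stream)]], tok$ids + 1L)
  for (i in seq_along(cfg$kernel_sizes)) {
    x <- tp_conv1d(tp, x, pid[[sprintf("cnn.%s.W%d", stream, i)]],
                   pid[[sprintf("cnn.%s.b%d", stream, i)]], cfg$kernel_sizes[i])
    x <- tp_relu(tp, x)
  }
  x
}

.tp_graph_encoder <- function(tp, pid, g, cfg) {
  d <- cfg$d
  E <- nrow(g$edges)
  atoms <- tp_push(tp, g$atom_features)
  if (E > 0L) {
    z0 <- tp_push(tp, cbind(g$atom_features[g$edges[, 1L], , drop = FALSE],
                            g$bond_features))
    h <- tp_relu(tp, tp_matmul(tp, z0, pid[["dmpnn.W_b"]]))
    p_proj <- tp_matmul(tp, atoms, pid[["dmpnn.W_x"]])
    for (t in seq_len(cfg$n_mpnn_iter)) {
      m <- tp_dmpnn_message(tp, h, p_proj, g$edges, g$rev_edge, cfg$message_fn)
      h <- tp_relu(tp, tp_linear(tp, tp_concat_cols(tp, c(h, m)),
                                 pid[["dmpnn.W_f"]], pid[["dmpnn.b_f"]]))
    }
    msum <- tp_rowsum_by(tp, h, g$edges[, 2L], g$n_atoms)
  } else {
    msum <- tp_push(tp, matrix(0, g$n_atoms, d))
  }
  tp_relu(tp, tp_matmul(tp, tp_concat_cols(tp, c(atoms, msum)),
                        pid[["dmpnn.W_alpha"]]))
}

.tp_attend_qkv <- function(tp, pid, key, xq, xkv, qmask, kmask, d_k) {
  q <- tp_linear(tp, xq, pid[[sprintf("attn.%s.W_Q", key)]],
                 pid[[sprintf("attn.%s.b_Q", key)]])
  k <- tp_linear(tp, xkv, pid[[sprintf("attn.%s.W_K", key)]],
                 pid[[sprintf("attn.%s.b_K", key)]])
  v <- tp_linear(tp, xkv, pid[[sprintf("attn.%s.W_V", key)]],
                 pid[[sprintf("attn.%s.b_V", key)]])
  tp_attend(tp, q, k, v, qmask, kmask, d_k)
}

# Forward pass for one featurized record; returns the probability node id.
.forward_sample <- function(tp, pid, model, feats, training = FALSE) {
  cfg <- model$config
  xs <- .tp_token_encoder(tp, pid, "smiles", feats$tok_smiles, cfg)
  xq <- .tp_token_encoder(tp, pid, "seq", feats$tok_seq, cfg)
  xm <- .tp_token_encoder(tp, pid, "mer", feats$tok_mer, cfg)
  xg <- .tp_graph_encoder(tp, pid, feats$graph, cfg)
  lens <- c(length(feats$tok_smiles$ids), feats$graph$n_atoms,
            length(feats$tok_seq$ids), length(feats$tok_mer$ids))
  masks <- list(feats$tok_smiles$mask, rep(TRUE, feats$graph$n_atoms),
                feats$tok_seq$mask, feats$tok_mer$mask)
  xlist <- list(xs, xg, xq, xm)

  pool_from <- function(nodes) {
    zs <- lapply(seq_along(nodes), function(i)
      tp_maxpool(tp, nodes[[i]], masks[[i]]))
    tp_concat_cols(tp, zs)
  }

  if (cfg$fusion_mode == "concat") {
    z <- pool_from(xlist)
  } else if (cfg$fusion_mode == "cross_attention") {
    # pairwise cross-attention inside each entity, then residual + pool
    ds <- .tp_attend_qkv(tp, pid, "l1d", xs, xg, masks[[1]], masks[[2]], cfg$d)$id
    dg <- .tp_attend_qkv(tp, pid, "l1d", xg, xs, masks[[2]], masks[[1]], cfg$d)$id
    dq <- .tp_attend_qkv(tp, pid, "l1p", xq, xm, masks[[3]], masks[[4]], cfg$d)$id
    dm <- .tp_attend_qkv(tp, pid, "l1p", xm, xq, masks[[4]], masks[[3]], cfg$d)$id
    fused <- list(tp_add(tp, ds, xs), tp_add(tp, dg, xg),
                  tp_add(tp, dq, xq), tp_add(tp, dm, xm))
    z <- pool_from(fused)
  } else {
    # level 1: drug stream (smiles|graph) and protein stream (seq|mer)
    xd <- tp_concat_rows(tp, c(xs, xg))
    xp <- tp_concat_rows(tp, c(xq, xm))
    md <- c(masks[[1]], masks[[2]]); mp <- c(masks[[3]], masks[[4]])
    h1d <- .tp_attend_qkv(tp, pid, "l1d", xd, xd, md, md, cfg$d)$id
    h1p <- .tp_attend_qkv(tp, pid, "l1p", xp, xp, mp, mp, cfg$d)$id
    # level 2: all four segments in order smiles|graph|seq|mer
    x2 <- tp_concat_rows(tp, c(h1d, h1p))
    m2 <- c(md, mp)
    h2 <- .tp_attend_qkv(tp, pid, "l2", x2, x2, m2, m2, cfg$d)$id
    ends <- cumsum(lens); starts <- c(1L, head(ends, -1L) + 1L)
    fused <- lapply(1:4, function(i) {
      d_i <- tp_subset_rows(tp, h2, starts[i]:ends[i])
      tp_add(tp, d_i, xlist[[i]])
    })
    z <- pool_from(fused)
  }

  for (i in 1:3) {
    z <- tp_linear(tp, z, pid[[sprintf("clf.W%d", i)]], pid[[sprintf("clf.b%d", i)]])
    z <- tp_dropout(tp, z, cfg$dropout, training)
    z <- tp_leaky_relu(tp, z, cfg$leaky_slope)
  }
  z <- tp_linear(tp, z, pid[["clf.W4"]], pid[["clf.b4"]])
  tp_sigmoid(tp, z)
}

# ---- public classifier / loss ---------------------------------------------

#' Classifier head on the pooled features
#'
#' Concatenates the four pooled vectors (width 4d) and applies four fully
#' connected layers; layers 1-3 are each followed by dropout and LeakyReLU,
#' the final layer outputs a single logit mapped through a sigmoid — applying
#' the activation after the last layer would destroy the logit, so it is
#' omitted there, as is dropout.
#'
#' @param z List with `Z_smiles`, `Z_graph`, `Z_seq`, `Z_mer` (length-d each),
#'   e.g. the `pooled` element of [hmsa_fuse()].
#' @param p A `classifier_params` (see [model_params()]).
#' @param training Enable dropout (default FALSE; inference is deterministic).
#' @return Interaction probability in (0, 1).
#' @export
classifier_forward <- function(z, p, training = FALSE) {
  v <- c(z$Z_smiles, z$Z_graph, z$Z_seq, z$Z_mer)
  if (length(v) != nrow(p$W1))
    stop_shape(sprintf("pooled width %d does not match classifier input %d",
                       length(v), nrow(p$W1)))
  x <- matrix(v, 1L)
  for (i in 1:3) {
    x <- sweep(x %*% p[[paste0("W", i)]], 2L, p[[paste0("b", i)]], "+")
    if (training && p$dropout > 0) {
      keep <- (stats::runif(length(x)) >= p$dropout) / (1 - p$dropout)
      x <- x * keep
    }
    x <- ifelse(x < 0, p$leaky_slope * x, x)
  }
  x <- sweep(x %*% p$W4, 2L, p$b4, "+")
  as.numeric(1 / (1 + exp(-x)))
}

#' Binary cross-entropy loss
#'
#' `L = -sum_i [ t_i log(p_i) + (1 - t_i) log(1 - p_i) ]`, with probabilities
#' clipped to `[eps, 1 - eps]`. The literal summed form is the default; the
#' `"mean"` reduction (sum / n) is what the training loop minimizes.
#'
#' @param t Labels in \{0, 1\}.
#' @param p Predicted probabilities.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @param eps Clipping epsilon (default 1e-7).
#' @return The loss value.
#' @export
#' @examples
#' bce_loss(1, 0.5)  # log(2)
bce_loss <- function(t, p, reduction = c("sum", "mean"), eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(t) != length(p)) stop_invalid("`t` and `p` must have equal length")
  if (!all(t %in% c(0, 1))) stop_invalid("labels must be 0 or 1")
  pc <- pmin(pmax(p, eps), 1 - eps)
  L <- -sum(t * log(pc) + (1 - t) * log(1 - pc))
  if (reduction == "mean") L / length(t) else L
}

# ---- prediction ------------------------------------------------------------

.as_records <- function(records) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("smiles", "sequence") %in% names(df)))
    stop_invalid("records need `smiles` and `sequence` columns")
  if (is.null(df$drug_id)) df$drug_id <- paste0("D", seq_len(nrow(df)))
  if (is.null(df$protein_id)) df$protein_id <- paste0("P", seq_len(nrow(df)))
  df
}

#' Score drug-protein pairs
#'
#' Featurizes every record through all four modalities and runs the full
#' model in evaluation mode (no dropout; deterministic). Records whose SMILES
#' cannot be parsed or whose sequence is empty are collected into a rejects
#' report instead of aborting the run.
#'
#' @param model A trained or freshly initialized `dti_model`.
#' @param records Data frame (or coercible) with columns `smiles`,
#'   `sequence`, optional `label`, `drug_id`, `protein_id`.
#' @return A `prediction_batch`: data.table in input order with a
#'   `probability` column (NA for rejected records); the rejects report
#'   (row index + reason) is in `attr(, "rejects")`.
#' @export
predict_pairs <- function(model, records) {
  df <- .as_records(records)
  n <- nrow(df)
  probs <- rep(NA_real_, n)
  rej_idx <- integer(0); rej_msg <- character(0)
  tp <- NULL
  for (i in seq_len(n)) {
    feats <- tryCatch(
      featurize_record(df$smiles[i], df$sequence[i], model$config),
      dtifuse_error = function(e) e)
    if (inherits(feats, "condition")) {
      rej_idx <- c(rej_idx, i); rej_msg <- c(rej_msg, conditionMessage(feats))
      next
    }
    tp <- new_tape()
    pid <- .tp_params(tp, model)
    probs[i] <- as.numeric(tp_val(tp, .forward_sample(tp, pid, model, feats,
                                                      training = FALSE)))
  }
  out <- data.table::data.table(df, probability = probs)
  rejects <- data.table::data.table(row = rej_idx, reason = rej_msg)
  data.table::setattr(out, "rejects", rejects)
  data.table::setattr(out, "class", c("prediction_batch", class(out)))
  out
}

#' Desk-scale configuration
#'
#' The package's declared settings for laptop/CI-scale experiments on the
#' synthetic benchmark: d = 32, T = 2, k = 2, 15 epochs, batch 50, Adam at
#' 1e-3 (about a hundred optimizer steps on a 400-record training split, so
#' the larger step size replaces the long 150-epoch schedule used at
#' benchmark scale).
#'
#' @param seed Seed (default 7, the synthetic benchmark's default).
#' @param ... Overrides passed to [dti_config()].
#' @return A `dti_config`.
#' @export
dti_desk_config <- function(seed = 7L, ...) {
  args <- list(d = 32L, epochs = 15L, batch_size = 50L, lr = 1e-3,
               seed = as.integer(seed))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dti_config, args)
}
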