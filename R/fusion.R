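# Multimodal fusion: masked scaled-dot-product attention as (a) cross-attention
# — the ablation baseline whose output is confined to the value modality's row
# span — and (b) two-level hierarchical multimodal self-attention, where two
# (then four) modality token streams are concatenated into one stream so the
# attention matrix realizes all intra- and inter-modal blocks at once.

#' Attention parameters
#'
#' Single linear maps for queries, keys and values, as in the printed
#' equations: `Q = X W_Q + b_Q` etc., with `d_k = d_att`. No layer
#' normalization or feed-forward sublayer is attached.
#'
#' @param d Input width.
#' @param d_att Attention width (default `d`; the residual connection in
#'   [hmsa_fuse()] requires `d_att == d`).
#' @param n_heads Number of attention heads (default 1, the faithful
#'   single-head form; must divide `d_att`).
#' @return An `attention_params` object.
#' @export
attention_params <- function(d, d_att = d, n_heads = 1L) {
  if (d_att %% n_heads != 0L)
    stop_invalid("`n_heads` must divide `d_att`")
  structure(list(
    W_Q = .glorot(d, d_att), b_Q = numeric(d_att),
    W_K = .glorot(d, d_att), b_K = numeric(d_att),
    W_V = .glorot(d, d_att), b_V = numeric(d_att),
    d = as.integer(d), d_att = as.integer(d_att), d_k = as.integer(d_att),
    n_heads = as.integer(n_heads)),
    class = "attention_params")
}

.fw_qkv <- function(Xq, Xkv, p) {
  list(Q = sweep(Xq %*% p$W_Q, 2L, p$b_Q, "+"),
       K = sweep(Xkv %*% p$W_K, 2L, p$b_K, "+"),
       V = sweep(Xkv %*% p$W_V, 2L, p$b_V, "+"))
}

# core: per-head masked softmax(QK^T / sqrt(d_head)) V
.fw_attention <- function(Q, K, V, qmask, kmask, n_heads = 1L, d_k = ncol(Q)) {
  if (n_heads == 1L) {
    A <- .fw_masked_softmax(tcrossprod(Q, K) / sqrt(d_k), qmask, kmask)
    return(list(H = A %*% V, A = A))
  }
  dh <- ncol(Q) %/% n_heads
  H <- matrix(0, nrow(Q), ncol(Q))
  As <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- .fw_masked_softmax(
      tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh),
      qmask, kmask)
    H[, cols] <- A %*% V[, cols, drop = FALSE]
    As[[h]] <- A
  }
  list(H = H, A = As)
}

.check_attn_input <- function(X, p) {
  if (ncol(X$values) != p$d)
    stop_shape(sprintf("input width %d does not match attention width %d",
                       ncol(X$values), p$d))
  if (!any(X$mask)) stop_invalid("all positions are masked")
}

#' Masked self-attention over one token stream
#'
#' `A = softmax(Q K' / sqrt(d_k))` row-wise over unmasked key positions
#' (masked keys get -Inf logits, hence exact zero weight); `H = A V`. Masked
#' query rows output zeros.
#'
#' @param X A `modal_matrix` with at least one unmasked position.
#' @param p An `attention_params` with `p$d == ncol(X$values)`.
#' @return An `attention_output`: list with `H` (L x d_att) and `A`
#'   (L x L attention weights; a list of per-head matrices when
#'   `n_heads > 1`).
#' @export
masked_self_attention <- function(X, p) {
  .check_attn_input(X, p)
  qkv <- .fw_qkv(X$values, X$values, p)
  out <- .fw_attention(qkv$Q, qkv$K, qkv$V, X$mask, X$mask, p$n_heads, p$d_k)
  out$H[!X$mask, ] <- 0
  structure(list(H = out$H, A = out$A), class = "attention_output")
}

#' Cross-attention between two modalities
#'
#' Queries come from `Xq`, keys and values from `Xkv`; each output row is a
#' convex combination of the rows of `V`, i.e. the fused feature lives in the
#' value modality's row span — the limitation that motivates the hierarchical
#' self-attention alternative.
#'
#' @param Xq Query `modal_matrix`.
#' @param Xkv Key/value `modal_matrix` (same width d).
#' @param p An `attention_params`.
#' @return An `attention_output` with `H` (L_q x d_att) and `A` (L_q x L_kv).
#' @export
cross_attention <- function(Xq, Xkv, p) {
  .check_attn_input(Xq, p)
  if (ncol(Xkv$values) != p$d) stop_shape("query and key/value widths differ")
  if (!any(Xkv$mask)) stop_invalid("key/value stream has no unmasked position")
  qkv <- .fw_qkv(Xq$values, Xkv$values, p)
  out <- .fw_attention(qkv$Q, qkv$K, qkv$V, Xq$mask, Xkv$mask, p$n_heads, p$d_k)
  out$H[!Xq$mask, ] <- 0
  structure(list(H = out$H, A = out$A), class = "attention_output")
}

#' One level of hierarchical multimodal self-attention
#'
#' Stacks the rows of `Xa` and `Xb` into a single token stream, applies masked
#' self-attention — so the attention matrix contains the a-a, a-b, b-a and b-b
#' blocks — and splits the output back at the boundary.
#'
#' @param Xa,Xb `modal_matrix` inputs of equal width.
#' @param p An `attention_params`.
#' @return List with `Ha` (L_a x d_att), `Hb` (L_b x d_att) and the joint
#'   attention matrix `A` ((L_a+L_b) x (L_a+L_b)).
#' @export
hmsa_level <- function(Xa, Xb, p) {
  if (ncol(Xa$values) != ncol(Xb$values))
    stop_shape("modalities must share the model width")
  La <- nrow(Xa$values)
  Xc <- new_modal_matrix(rbind(Xa$values, Xb$values), c(Xa$mask, Xb$mask))
  out <- masked_self_attention(Xc, p)
  list(Ha = out$H[seq_len(La), , drop = FALSE],
       Hb = out$H[-seq_len(La), , drop = FALSE],
       A = out$A)
}

#' Two-level hierarchical multimodal self-attention with residual + max-pool
#'
#' Level 1 fuses the two drug streams (SMILES, graph) and, separately, the two
#' protein streams (sequence, k-mer). Level 2 concatenates the level-1 drug
#' and protein outputs — all four segments in order smiles | graph | seq | mer
#' — and applies self-attention again. The output splits back into the four
#' per-modality matrices `D_*`, each is added to its encoder input `X_*`
#' (residual), and a masked max-pool over real positions yields the four
#' pooled vectors `Z_*` that feed the classifier.
#'
#' @param X_smiles,X_graph,X_seq,X_mer Encoder outputs (`modal_matrix`, common
#'   width d, each with at least one unmasked position).
#' @param p_level1_drug,p_level1_protein,p_level2 `attention_params` for the
#'   three attention modules (parameters are not shared).
#' @return List with `pooled` (list `Z_smiles`, `Z_graph`, `Z_seq`, `Z_mer`,
#'   each length d), `bundle` (list of the four `D_*` matrices, shapes
#'   matching their `X_*`), and `attention` (the three attention matrices).
#' @export
hmsa_fuse <- function(X_smiles, X_graph, X_seq, X_mer,
                      p_level1_drug, p_level1_protein, p_level2) {
  xs <- list(smiles = X_smiles, graph = X_graph, seq = X_seq, mer = X_mer)
  for (nm in names(xs))
    if (!any(xs[[nm]]$mask))
      stop_invalid(sprintf("modality '%s' has no unmasked position", nm))
  l1d <- hmsa_level(X_smiles, X_graph, p_level1_drug)
  l1p <- hmsa_level(X_seq, X_mer, p_level1_protein)
  lens <- vapply(xs, function(x) nrow(x$values), integer(1))
  mask_all <- c(X_smiles$mask, X_graph$mask, X_seq$mask, X_mer$mask)
  X2 <- new_modal_matrix(rbind(l1d$Ha, l1d$Hb, l1p$Ha, l1p$Hb), mask_all)
  l2 <- masked_self_attention(X2, p_level2)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  bundle <- pooled <- list()
  for (i in seq_along(xs)) {
    nm <- names(xs)[i]
    D <- l2$H[starts[i]:ends[i], , drop = FALSE]
    bundle[[paste0("D_", nm)]] <- D
    R <- D + xs[[nm]]$values
    z <- apply(R[xs[[nm]]$mask, , drop = FALSE], 2L, max)
    pooled[[paste0("Z_", nm)]] <- z
  }
  list(pooled = pooled, bundle = bundle,
       attention = list(level1_drug = l1d$A, level1_protein = l1p$A,
                        level2 = l2$A))
}

#' Export an attention matrix as delimited text
#'
#' Long format (query index, key index, weight) for auditing the intra- and
#' inter-modal blocks.
#'
#' @param A Attention matrix (or `attention_output`).
#' @param path Output TSV path.
#' @param keep_zero Keep exact-zero (masked) entries (default FALSE).
#' @return The data.table written, invisibly.
#' @export
write_attention <- function(A, path, keep_zero = FALSE) {
  if (inherits(A, "attention_output")) A <- A$A
  dt <- data.frame(
    query = rep(seq_len(nrow(A)), times = ncol(A)),
    key = rep(seq_len(ncol(A)), each = nrow(A)),
    weight = as.numeric(A))
  if (!keep_zero) dt <- dt[dt$weight != 0, ]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(dt)
}
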