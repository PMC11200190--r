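# Token-level featurization: protein sequences, protein k-mers and SMILES
# strings become fixed-length padded integer vectors ("token vectors"); id 0 is
# padding everywhere and padding is always a suffix.

#' Construct a token vector
#'
#' @param ids Integer vector: the first `true_length` entries are token ids
#'   (>= 1), the rest zeros.
#' @param true_length Number of real (non-padding) tokens.
#' @return A `token_vector`: list with `ids`, logical `mask` and `true_length`.
#' @keywords internal
new_token_vector <- function(ids, true_length) {
  ids <- as.integer(ids)
  mask <- seq_along(ids) <= true_length
  structure(list(ids = ids, mask = mask, true_length = as.integer(true_length)),
            class = "token_vector")
}

#' @export
print.token_vector <- function(x, ...) {
  cat(sprintf("<token_vector> length %d (%d real tokens)\n",
              length(x$ids), x$true_length))
  invisible(x)
}

.seq_to_ids <- function(seq) {
  ab <- residue_alphabet()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ids <- ab$index[chars]
  ids[is.na(ids)] <- ab$index[[ab$fallback]]
  unname(ids)
}

#' Encode a protein sequence as a padded token vector
#'
#' Residues map to integer ids 1..22 via [residue_alphabet()]; characters
#' outside the alphabet are normalized to the fallback symbol `X`. Sequences
#' longer than `L_max` keep their prefix; shorter ones are zero-padded.
#'
#' @param seq Non-empty one-letter residue string.
#' @param L_max Fixed output length (default 1000).
#' @return A `token_vector` of length `L_max`.
#' @export
#' @examples
#' encode_protein_sequence("MKV", L_max = 5)$ids
encode_protein_sequence <- function(seq, L_max = 1000L) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_invalid("`seq` must be a non-empty residue string")
  if (L_max < 1L) stop_invalid("`L_max` must be >= 1")
  ids <- .seq_to_ids(seq)
  n <- min(length(ids), L_max)
  out <- integer(L_max)
  out[seq_len(n)] <- ids[seq_len(n)]
  new_token_vector(out, n)
}

#' Tokenize a protein sequence into overlapping k-mers
#'
#' A window of length `k` slides left to right one residue at a time, so a
#' length-N sequence yields N - k + 1 k-mer tokens (before padding or
#' truncation to `L_max`). The token id of the k-mer a1..ak is the positional
#' base-22 code `sum_j (id(a_j) - 1) * 22^(k - j) + 1`, a bijection onto
#' 1..22^k.
#'
#' @param seq Residue string of length >= k.
#' @param k k-mer length, 1, 2 or 3 (k = 4 is rejected: the 234 256-token
#'   vocabulary makes the embedding table impractical).
#' @param L_max Fixed output length (default 999 = 1000 - k + 1 at k = 2).
#' @return A `token_vector` of length `L_max`.
#' @export
#' @examples
#' make_kmer_tokens("ACDEF", k = 2, L_max = 6)$ids
make_kmer_tokens <- function(seq, k = 2L, L_max = 999L) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_invalid("`seq` must be a non-empty residue string")
  if (!k %in% 1:3) stop_invalid("`k` must be 1, 2 or 3")
  ids <- .seq_to_ids(seq)
  n <- length(ids)
  if (n < k) stop_invalid(sprintf("sequence length %d is shorter than k = %d", n, k))
  n_tok <- n - k + 1L
  tok <- rep(1, n_tok)
  for (j in seq_len(k)) tok <- tok + (ids[j:(j + n_tok - 1L)] - 1) * 22^(k - j)
  m <- min(n_tok, L_max)
  out <- integer(L_max)
  out[seq_len(m)] <- as.integer(tok[seq_len(m)])
  new_token_vector(out, m)
}

#' Tokenize a SMILES string character-wise
#'
#' Each character maps to an integer id in 1..64 via [smiles_alphabet()]; the
#' vector is zero-padded (or prefix-truncated) to `L_max`.
#'
#' @param smiles Non-empty SMILES string.
#' @param L_max Fixed output length (default 150).
#' @param unk_policy Passed to [smiles_alphabet()]: `"error"` (default) or
#'   `"reserved"` for characters outside the 64-symbol set.
#' @return A `token_vector` of length `L_max`.
#' @export
tokenize_smiles <- function(smiles, L_max = 150L, unk_policy = c("error", "reserved")) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop_invalid("`smiles` must be a non-empty string")
  ab <- smiles_alphabet(unk_policy)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  ids <- ab$index[chars]
  if (anyNA(ids)) {
    if (ab$unk_policy == "error") {
      bad <- unique(chars[is.na(ids)])
      stop_invalid(sprintf("SMILES character(s) outside the 64-symbol alphabet: %s",
                           paste(sQuote(bad), collapse = ", ")))
    }
    ids[is.na(ids)] <- ab$index[["*"]]
  }
  n <- min(length(ids), L_max)
  out <- integer(L_max)
  out[seq_len(n)] <- ids[seq_len(n)]
  new_token_vector(out, n)
}

#' Decode a token vector back to characters
#'
#' Inverse of the per-symbol encoders over real (unmasked) positions; mainly a
#' round-trip check for the frozen alphabets.
#'
#' @param tokens A `token_vector` produced by [encode_protein_sequence()] or
#'   [tokenize_smiles()].
#' @param alphabet `"residue"` or `"smiles"`.
#' @return Single string of decoded symbols.
#' @export
decode_tokens <- function(tokens, alphabet = c("residue", "smiles")) {
  alphabet <- match.arg(alphabet)
  syms <- if (alphabet == "residue") residue_alphabet()$symbols else smiles_alphabet()$chars
  ids <- tokens$ids[tokens$mask]
  paste(syms[ids], collapse = "")
}
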