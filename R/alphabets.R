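# Frozen symbol alphabets. Token ids must be bit-exact across versions, so both
# alphabets live as plain-text constant files (one symbol per line) under
# inst/extdata and are only read, never derived.

.dtifuse_env <- new.env(parent = emptyenv())

.read_alphabet <- function(fname) {
  path <- system.file("extdata", fname, package = "dtifuse")
  if (!nzchar(path)) path <- file.path("inst", "extdata", fname)
  readLines(path, warn = FALSE)
}

#' Residue alphabet (22 symbols)
#'
#' The protein vocabulary: the 20 standard amino acids plus selenocysteine
#' (`U`) and the unknown/ambiguity symbol `X`. Ids are 1..22 in file order;
#' id 0 is reserved for padding and never assigned to a residue. Any character
#' outside the alphabet is normalized to the fallback symbol `X` before
#' encoding.
#'
#' @return A list with `symbols` (character vector of length 22), `pad_id`
#'   (always `0L`), `fallback` (`"X"`), and `index` (named integer vector
#'   mapping each symbol to its id).
#' @export
#' @examples
#' residue_alphabet()$symbols
residue_alphabet <- function() {
  if (is.null(.dtifuse_env$residue)) {
    symbols <- .read_alphabet("residue_alphabet.txt")
    stopifnot(length(symbols) == 22L, !anyDuplicated(symbols))
    index <- seq_along(symbols)
    names(index) <- symbols
    .dtifuse_env$residue <- list(symbols = symbols, pad_id = 0L,
                                 fallback = "X", index = index)
  }
  .dtifuse_env$residue
}

#' SMILES character alphabet (64 symbols)
#'
#' A fixed 64-character label-encoding set for SMILES strings: digits,
#' upper/lowercase letters of the organic and two-letter element subsets, and
#' bond/ring/branch/charge/stereo punctuation. Characters map to ids 1..64 in
#' file order; 0 is reserved for padding.
#'
#' @param unk_policy What to do with a character absent from the alphabet:
#'   `"error"` (default) raises an invalid-input error naming the character;
#'   `"reserved"` maps it to the reserved wildcard id (the `*` character).
#' @return A list with `chars`, `pad_id`, `unk_policy` and `index`.
#' @export
smiles_alphabet <- function(unk_policy = c("error", "reserved")) {
  unk_policy <- match.arg(unk_policy)
  if (is.null(.dtifuse_env$smiles)) {
    chars <- .read_alphabet("smiles_alphabet.txt")
    stopifnot(length(chars) == 64L, !anyDuplicated(chars))
    index <- seq_along(chars)
    names(index) <- chars
    .dtifuse_env$smiles <- list(chars = chars, pad_id = 0L, index = index)
  }
  out <- .dtifuse_env$smiles
  out$unk_policy <- unk_policy
  out
}

#' k-mer vocabulary size
#'
#' Number of distinct k-mer tokens over the 22-symbol residue alphabet,
#' excluding the padding id: `22^k` (22, 484, 10648, 234256 for k = 1..4).
#'
#' @param k k-mer length, a positive integer.
#' @return `22^k` as a double (the k = 4 vocabulary exceeds `.Machine$integer.max / 9`).
#' @export
#' @examples
#' kmer_vocab_size(2) # 484
kmer_vocab_size <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k))
    stop_invalid("`k` must be a single integer >= 1")
  22^as.integer(k)
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("dtifuse_invalid_input", "dtifuse_error")))
}

stop_shape <- function(msg) {
  stop(errorCondition(msg, class = c("dtifuse_shape_error", "dtifuse_error")))
}
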