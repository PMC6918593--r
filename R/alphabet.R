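# Amino-acid alphabet and language-model token vocabulary.
#
# Proteins are treated as sentences whose words are single residues. The
# residue alphabet has 25 letters: the 20 standard amino acids, the two rare
# ones (U, O), the two ambiguity codes (B, Z) and the unknown code (X).
# The LM vocabulary adds three special tokens (padding/mask, sequence start,
# sequence end) for a total of 28 tokens.

#' Amino-acid alphabet used throughout the package
#'
#' Returns the 25-letter residue alphabet: 20 canonical amino acids
#' (alphabetical one-letter codes), the rare residues selenocysteine (U) and
#' pyrrolysine (O), the ambiguity codes B (Asx) and Z (Glx), and X (unknown).
#'
#' @return An object of class \code{aa_alphabet}: a list with elements
#'   \code{standard} (character vector of 20), \code{rare} (U, O),
#'   \code{ambiguous} (B, Z), \code{unknown} (X) and \code{letters}
#'   (all 25 in canonical order).
#' @export
#' @examples
#' length(aa_alphabet()$letters)  # 25
aa_alphabet <- function() {
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rare <- c("U", "O")
  ambiguous <- c("B", "Z")
  unknown <- "X"
  stopifnot(length(unique(standard)) == 20L)
  structure(
    list(
      standard = standard, rare = rare, ambiguous = ambiguous,
      unknown = unknown,
      letters = c(standard, rare, ambiguous, unknown)
    ),
    class = "aa_alphabet"
  )
}

#' Build the 28-token language-model vocabulary
#'
#' The vocabulary covers the 25 residue letters plus three special tokens:
#' \code{<pad>} (padding/mask), \code{<s>} (sequence start) and \code{</s>}
#' (sequence end). Indices are contiguous from 0 in a fixed, documented
#' order — special tokens first (pad = 0, start = 1, end = 2), then the 20
#' standard residues alphabetically, then U, O, B, Z, X — so stored models
#' and embeddings are portable across runs.
#'
#' @param alphabet An \code{aa_alphabet}, by default \code{aa_alphabet()}.
#' @return An object of class \code{token_vocab}: list with \code{tokens}
#'   (character vector of 28, position i holds the token with index i - 1),
#'   \code{index} (named integer vector token -> 0-based index),
#'   \code{pad}, \code{start}, \code{end} (0-based special indices) and
#'   \code{size} (28).
#' @export
#' @examples
#' v <- build_vocabulary()
#' v$size                      # 28
#' v$index[["A"]]              # 3
build_vocabulary <- function(alphabet = aa_alphabet()) {
  stopifnot(inherits(alphabet, "aa_alphabet"))
  specials <- c("<pad>", "<s>", "</s>")
  tokens <- c(specials, alphabet$letters)
  if (anyDuplicated(tokens)) {
    stop("special tokens collide with residue letters")
  }
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  structure(
    list(
      tokens = tokens, index = idx,
      pad = 0L, start = 1L, end = 2L,
      size = length(tokens)
    ),
    class = "token_vocab"
  )
}

#' Canonicalize a raw residue string
#'
#' Uppercases, strips whitespace and the stop-codon symbol \code{*}, and
#' replaces every character outside the 25-letter alphabet by \code{X}.
#' Alignment gap characters (\code{-}, \code{.}) are rejected: alignment
#' input is out of scope.
#'
#' @param raw A single character string.
#' @return The canonical sequence, with attribute \code{n_replaced} giving
#'   the number of X substitutions performed.
#' @export
#' @examples
#' canonicalize_sequence("acdef")   # "ACDEF"
canonicalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  s <- toupper(gsub("[[:space:]*]", "", raw))
  if (nchar(s) == 0L) {
    stop("sequence is empty after stripping whitespace and '*'")
  }
  chars <- strsplit(s, "")[[1]]
  if (any(chars %in% c("-", "."))) {
    stop("gap characters ('-', '.') found: aligned input is not supported")
  }
  bad <- !(chars %in% aa_alphabet()$letters)
  chars[bad] <- "X"
  out <- paste(chars, collapse = "")
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Tokenize a protein sequence for the language model
#'
#' Maps a canonical residue string to 0-based vocabulary indices, bracketed
#' by the start and end tokens, so a length-L protein becomes L + 2 indices.
#'
#' @param sequence Canonical residue string (see
#'   \code{\link{canonicalize_sequence}}).
#' @param vocab A \code{token_vocab}.
#' @return Integer vector of length \code{nchar(sequence) + 2}.
#' @export
tokenize <- function(sequence, vocab = build_vocabulary()) {
  stopifnot(inherits(vocab, "token_vocab"))
  chars <- strsplit(sequence, "")[[1]]
  pos <- match(chars, vocab$tokens)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    stop(sprintf("character '%s' at position %d is not in the vocabulary",
                 chars[i], i))
  }
  c(vocab$start, pos - 1L, vocab$end)
}

#' Invert \code{\link{tokenize}}
#'
#' @param indices 0-based token indices, bracketed by start/end.
#' @param vocab A \code{token_vocab}.
#' @return The residue string (special tokens dropped).
#' @export
detokenize <- function(indices, vocab = build_vocabulary()) {
  stopifnot(all(indices >= 0L), all(indices < vocab$size))
  body <- indices[!(indices %in% c(vocab$pad, vocab$start, vocab$end))]
  paste(vocab$tokens[body + 1L], collapse = "")
}
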