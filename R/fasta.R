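# FASTA reading/writing via Biostrings, with canonicalization and the
# record contract used across the package: a data.frame with columns
# `id` (unique) and `sequence` (canonical 25-letter residue strings).

#' Read protein records from a FASTA file
#'
#' Wraps \code{Biostrings::readAAStringSet}. Record ids are the first
#' whitespace-delimited header token; sequences are canonicalized with
#' \code{\link{canonicalize_sequence}} (uppercased, \code{*} stripped,
#' out-of-alphabet characters replaced by X). Order is preserved.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @return A data.frame of class \code{protein_records} with columns
#'   \code{id} and \code{sequence}, plus attribute \code{n_replaced}
#'   (total X substitutions made during canonicalization).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    return(protein_records(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(aas), "[[:space:]]+"), `[`, "", 1L)
  raw <- as.character(aas)
  empty <- !nzchar(raw)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  n_rep <- 0L
  seqs <- vapply(raw, function(s) {
    cs <- canonicalize_sequence(s)
    n_rep <<- n_rep + attr(cs, "n_replaced")
    as.character(cs)
  }, "", USE.NAMES = FALSE)
  out <- protein_records(ids, seqs)
  attr(out, "n_replaced") <- n_rep
  out
}

#' Construct a protein_records data.frame
#'
#' @param id Character vector of unique record ids.
#' @param sequence Character vector of canonical residue strings.
#' @return A \code{protein_records} data.frame.
#' @export
protein_records <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("record ids must be unique")
  if (length(sequence) > 0L && any(!nzchar(sequence))) {
    stop("sequences must be non-empty")
  }
  structure(
    data.frame(id = as.character(id), sequence = as.character(sequence),
               stringsAsFactors = FALSE),
    class = c("protein_records", "data.frame")
  )
}

#' Write protein records to FASTA
#'
#' @param records A \code{protein_records} data.frame.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aas <- Biostrings::AAStringSet(records$sequence)
  names(aas) <- records$id
  Biostrings::writeXStringSet(aas, filepath = path, width = width)
  invisible(path)
}
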