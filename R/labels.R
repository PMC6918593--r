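# Label conventions: DSSP eight-state -> three-state reduction and the
# disorder-from-missing-coordinates rule.

#' Map DSSP eight-state letters to three states
#'
#' Uses the common convention: G, H, I -> H (helix); B, E -> E (strand);
#' everything else (T, S, C and the unknown marker) -> O (other).
#'
#' @param label Character vector of single eight-state letters
#'   (H, G, I, E, B, T, S, C) or the unknown marker \code{"-"}.
#' @return Character vector of three-state letters (H, E, O).
#' @export
#' @examples
#' map_dssp8_to_3(c("G", "B", "T"))  # "H" "E" "O"
map_dssp8_to_3 <- function(label) {
  allowed <- c("H", "G", "I", "E", "B", "T", "S", "C", "-")
  bad <- setdiff(unique(label), allowed)
  if (length(bad) > 0L) {
    stop("not an eight-state letter: ", paste(bad, collapse = ", "))
  }
  out <- rep("O", length(label))
  out[label %in% c("G", "H", "I")] <- "H"
  out[label %in% c("B", "E")] <- "E"
  out
}

#' Map an eight-state label string to its three-state string
#'
#' @param s A string of eight-state letters.
#' @return The corresponding three-state string.
#' @export
map_dssp8_to_3_string <- function(s) {
  paste(map_dssp8_to_3(strsplit(s, "")[[1]]), collapse = "")
}

#' Derive disorder labels from coordinate presence
#'
#' A residue is intrinsically disordered exactly when it has no atomic
#' coordinates in the deposited structure.
#'
#' @param present Logical vector: TRUE where coordinates are present.
#' @return Integer vector: 1 = disordered, 0 = ordered.
#' @export
disorder_from_coordinates <- function(present) {
  stopifnot(is.logical(present), !anyNA(present))
  as.integer(!present)
}
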