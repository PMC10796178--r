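#' The canonical amino-acid alphabet
#'
#' The package works over a fixed 21-symbol alphabet: the 20 standard amino
#' acids in alphabetical one-letter order, followed by `X` for unknown
#' residues. Every index used anywhere in the package (pair-code formula,
#' embedding rows, motif matrix columns) derives from this single constant,
#' so encodings are reproducible across runs and platforms.
#'
#' @return A character vector of length 21 ending in `"X"`.
#' @examples
#' amino_alphabet()
#' @export
amino_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

# fixed string form, used by the fast index lookups below
.ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

#' The padding character used when peptides are filled to a fixed length
#'
#' Padding is deliberately distinct from the unknown-residue symbol `X`:
#' absent positions carry no residue information, whereas `X` asserts an
#' unidentified residue is present. In the encoded interaction matrix pad
#' positions map to code 0, which the model embeds as a frozen zero vector.
#'
#' @return A single character, `"-"`.
#' @export
pad_char <- function() "-"

#' Positions of residues in the canonical alphabet
#'
#' @param residues Character vector of single residue characters, or a single
#'   string to be split into characters.
#' @return Integer vector of 1-based positions in [amino_alphabet()];
#'   `NA` for characters outside the alphabet (including the pad character).
#' @keywords internal
aa_index <- function(residues) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "", fixed = TRUE)[[1]]
  }
  idx <- match(residues, strsplit(.ALPHABET, "", fixed = TRUE)[[1]])
  as.integer(idx)
}

#' Replace non-alphabet residues with X
#'
#' Uppercases the input and maps every character outside the 21-symbol
#' alphabet to `X`. Used at every ingestion point (affinity tables, FASTA)
#' so downstream code only ever sees canonical residues.
#'
#' @param x Character vector of sequences.
#' @return A list with `seq` (cleaned sequences) and `n_replaced` (total
#'   count of substituted characters across all sequences).
#' @keywords internal
sanitize_residues <- function(x) {
  x <- toupper(x)
  cleaned <- gsub(sprintf("[^%s]", .ALPHABET), "X", x)
  n_replaced <- sum(nchar(x) - nchar(gsub(sprintf("[^%s]", .ALPHABET), "", x)))
  list(seq = cleaned, n_replaced = as.integer(n_replaced))
}

#' Check that sequences contain only alphabet residues
#' @keywords internal
is_valid_sequence <- function(x) {
  !grepl(sprintf("[^%s]", .ALPHABET), x) & nchar(x) >= 1L
}
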