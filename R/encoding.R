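#' Build the residue-residue pair vocabulary
#'
#' Every ordered pair of alphabet symbols (an MHC residue paired with a
#' peptide residue) gets its own positive integer code. With 21 symbols
#' there are 21 x 21 = 441 coded pairs; the mapping must be bijective and
#' order-sensitive, so the pair (a, b) and its reverse (b, a) receive
#' different codes whenever a != b. The concrete bijection used here is
#' row-major in canonical alphabet order:
#' \deqn{code(a_i, b_j) = (i - 1) \cdot 21 + j}
#' with `i`, `j` the 1-based alphabet positions. Code 0 is reserved for
#' padding and maps to no residue pair. Any fixed bijection is behaviourally
#' equivalent for the model; freezing this one makes stored encodings and
#' checkpoints portable (`vocabulary_version()` names the formula).
#'
#' @return An object of class `rpe_vocabulary` with elements `pairs`
#'   (tibble: `mhc`, `pep`, `code`), `size` (441) and `version`.
#' @examples
#' v <- build_vocabulary()
#' v$size
#' pair_code("A", "C", v)
#' @export
build_vocabulary <- function() {
  ab <- amino_alphabet()
  grid <- expand.grid(j = seq_along(ab), i = seq_along(ab))
  pairs <- tibble::tibble(
    mhc = ab[grid$i],
    pep = ab[grid$j],
    code = (grid$i - 1L) * length(ab) + grid$j
  )
  pairs <- pairs[order(pairs$code), ]
  structure(
    list(pairs = pairs, size = nrow(pairs), version = vocabulary_version()),
    class = "rpe_vocabulary"
  )
}

#' Version tag of the pair-code formula
#'
#' Stored in checkpoints and exported encodings so that persisted integer
#' grids are self-describing; loading refuses on mismatch.
#' @return A single string.
#' @export
vocabulary_version <- function() "rowmajor-ACDEFGHIKLMNPQRSTVWYX-v1"

#' @export
print.rpe_vocabulary <- function(x, ...) {
  cat("<rpe_vocabulary> ", x$size, " ordered residue pairs, formula ",
      x$version, "\n", sep = "")
  invisible(x)
}

#' Code of an ordered residue pair
#'
#' @param mhc,pep Single characters (vectorised) from the alphabet.
#' @param vocab A vocabulary from [build_vocabulary()].
#' @return Integer codes in 1..441.
#' @export
pair_code <- function(mhc, pep, vocab = build_vocabulary()) {
  i <- aa_index(mhc)
  j <- aa_index(pep)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("Residue outside the alphabet.", call. = FALSE)
  }
  (i - 1L) * 21L + j
}

#' Residue pair of a code
#' @param code Integer vector in 1..441.
#' @param vocab A vocabulary from [build_vocabulary()].
#' @return A tibble with columns `mhc`, `pep`.
#' @export
code_pair <- function(code, vocab = build_vocabulary()) {
  if (any(code < 1L | code > 441L)) stop("Codes must be in 1..441.", call. = FALSE)
  ab <- amino_alphabet()
  i <- (code - 1L) %/% 21L + 1L
  j <- (code - 1L) %% 21L + 1L
  tibble::tibble(mhc = ab[i], pep = ab[j])
}

#' Encode one MHC / peptide pair as a 34 x 20 interaction matrix
#'
#' Entry (i, j) holds the integer code of the ordered pair (MHC residue i,
#' peptide residue j). Rows are the 34 pseudo-sequence positions, columns
#' the 20 peptide positions. Columns beyond the peptide's raw length are
#' padding and are entirely 0.
#'
#' @param pseudo A 34-residue MHC pseudo-sequence string.
#' @param peptide A peptide already normalized to length 20 (see
#'   [normalize_peptide()]); an un-normalized peptide is an error.
#' @param vocab A vocabulary from [build_vocabulary()].
#' @return An integer matrix of class `interaction_matrix`, dim c(34, 20),
#'   with attributes `raw_length` and `vocab_version`.
#' @examples
#' p <- normalize_peptide("ACDEFGHIK")
#' m <- encode_pair(strrep("A", 34), p$peptide)
#' dim(m)
#' @export
encode_pair <- function(pseudo, peptide, vocab = build_vocabulary()) {
  if (nchar(pseudo) != 34L || !is_valid_sequence(pseudo)) {
    stop("`pseudo` must be a 34-residue string over the alphabet.", call. = FALSE)
  }
  if (nchar(peptide) != 20L) {
    stop("`peptide` must be normalized to length 20 (see normalize_peptide()).",
         call. = FALSE)
  }
  pep_chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  pad <- pep_chars == pad_char()
  if (any(pad) && (pad[1] || any(diff(pad) < 0))) {
    stop("Padding must be a contiguous suffix of the peptide.", call. = FALSE)
  }
  j <- aa_index(pep_chars)
  if (any(is.na(j) & !pad)) stop("Peptide residue outside the alphabet.", call. = FALSE)
  i <- aa_index(pseudo)
  if (any(is.na(i))) stop("Pseudo-sequence residue outside the alphabet.", call. = FALSE)
  m <- outer(i - 1L, ifelse(pad, NA_integer_, j), function(a, b) a * 21L + b)
  m[, pad] <- 0L
  storage.mode(m) <- "integer"
  structure(m,
            raw_length = sum(!pad),
            vocab_version = vocab$version,
            class = c("interaction_matrix", class(m)))
}

#' Decode an interaction matrix back to its sequences
#'
#' Exercises the bijectivity of the pair coding: the 34-mer pseudo-sequence
#' and the unpadded peptide are recovered exactly, and inconsistent matrices
#' (cells that imply conflicting residues) are rejected.
#'
#' @param m An `interaction_matrix` (or plain 34 x 20 integer matrix).
#' @param vocab A vocabulary from [build_vocabulary()].
#' @return A list with `pseudo` (34-mer) and `peptide` (unpadded string).
#' @export
decode_matrix <- function(m, vocab = build_vocabulary()) {
  if (!is.matrix(m) || !all(dim(m) == c(34L, 20L))) {
    stop("Expected a 34 x 20 matrix.", call. = FALSE)
  }
  if (any(m < 0L | m > 441L)) stop("Codes must be in 0..441.", call. = FALSE)
  pad_col <- apply(m == 0L, 2, all)
  mixed <- apply(m == 0L, 2, any) & !pad_col
  if (any(mixed)) stop("Inconsistent matrix: partially padded column.", call. = FALSE)
  if (all(pad_col)) stop("Inconsistent matrix: no non-pad column.", call. = FALSE)
  if (any(pad_col) && (pad_col[1] || any(diff(pad_col) < 0))) {
    stop("Inconsistent matrix: pad columns must be a suffix.", call. = FALSE)
  }
  ab <- amino_alphabet()
  live <- which(!pad_col)
  i_idx <- (m[, live, drop = FALSE] - 1L) %/% 21L + 1L
  j_idx <- (m[, live, drop = FALSE] - 1L) %% 21L + 1L
  # each row must imply a single MHC residue; each column a single peptide residue
  if (any(apply(i_idx, 1, function(r) length(unique(r))) != 1L) ||
      any(apply(j_idx, 2, function(cl) length(unique(cl))) != 1L)) {
    stop("Inconsistent matrix: conflicting residue implications.", call. = FALSE)
  }
  list(pseudo = paste(ab[i_idx[, 1]], collapse = ""),
       peptide = paste(ab[j_idx[1, ]], collapse = ""))
}

#' Encode a dataset of (allele, peptide) rows for the model
#'
#' Produces the flat integer code layout the network consumes: one row per
#' record, 680 columns holding the 34 x 20 matrix in column-major order
#' (matrix cell (i, j) at flat position i + 34 (j - 1)).
#'
#' @param data Tibble with columns `allele` and `peptide`.
#' @param pseudo_map Tibble with columns `allele`, `pseudo` (see
#'   [read_pseudosequence_table()]).
#' @param vocab A vocabulary.
#' @return An integer matrix n x 680 with attribute `raw_length`.
#' @export
encode_dataset <- function(data, pseudo_map, vocab = build_vocabulary()) {
  missing <- setdiff(unique(data$allele), pseudo_map$allele)
  if (length(missing)) {
    stop("Unknown allele(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  norm <- normalize_peptide(data$peptide)
  pep_idx <- aa_index_matrix(norm$peptide)                 # n x 20, NA at pads
  pseudo <- pseudo_map$pseudo[match(data$allele, pseudo_map$allele)]
  mhc_idx <- aa_index_matrix(pseudo)                       # n x 34
  n <- nrow(pep_idx)
  codes <- matrix(0L, n, 680L)
  for (j in seq_len(20L)) {
    pj <- pep_idx[, j]
    block <- (mhc_idx - 1L) * 21L + matrix(pj, n, 34L)
    block[is.na(pj), ] <- 0L
    codes[, (j - 1L) * 34L + seq_len(34L)] <- block
  }
  attr(codes, "raw_length") <- norm$raw_length
  codes
}

# character matrix of alphabet indices for equal-length strings; NA for pads
aa_index_matrix <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)
  mat <- do.call(rbind, lapply(chars, aa_index))
  mat
}

#' Export encoded interaction matrices as self-describing text
#'
#' Writes a header recording the alphabet order and pair-code formula
#' version, followed by one whitespace-delimited 34 x 20 integer grid per
#' record.
#'
#' @param mats A list of `interaction_matrix` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoding <- function(mats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# rpemhc interaction-matrix export v1",
    paste0("# alphabet: ", paste(amino_alphabet(), collapse = "")),
    paste0("# vocabulary: ", vocabulary_version()),
    paste0("# n: ", length(mats))
  ), con)
  for (m in mats) {
    writeLines(paste0("# raw_length: ", attr(m, "raw_length")), con)
    utils::write.table(unclass(m), con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read interaction matrices exported with [write_encoding()]
#' @param path File path.
#' @return A list of `interaction_matrix` objects.
#' @export
read_encoding <- function(path) {
  lines <- readLines(path)
  voc <- sub("^# vocabulary: ", "", grep("^# vocabulary: ", lines, value = TRUE))
  if (!identical(voc, vocabulary_version())) {
    stop("Vocabulary version mismatch: file has '", voc, "', package uses '",
         vocabulary_version(), "'.", call. = FALSE)
  }
  starts <- grep("^# raw_length: ", lines)
  lapply(starts, function(s) {
    rl <- as.integer(sub("^# raw_length: ", "", lines[s]))
    block <- lines[(s + 1L):(s + 34L)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.integer))
    structure(m, raw_length = rl, vocab_version = vocabulary_version(),
              class = c("interaction_matrix", class(m)))
  })
}
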