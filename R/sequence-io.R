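#' Transform raw IC50 values to the unit interval
#'
#' Binding affinity assays report IC50 in nanomolar, where lower means
#' stronger binding. The conventional transform
#' \deqn{y = 1 - \log(\mathrm{IC50})/\log(50000)}
#' maps IC50 values onto a 0--1 scale (1 nM -> 1, 50 000 nM -> 0). Values
#' below 0 (IC50 above 50 000 nM) or above 1 (IC50 below 1 nM) are clamped
#' at ingestion so that labels always lie in \[0, 1\]. The transform is
#' base-invariant; natural logarithms are used.
#'
#' @param ic50_nM Numeric vector of positive IC50 values in nM.
#' @return Numeric vector of transformed affinities in \[0, 1\].
#' @examples
#' transform_ic50(c(1, 500, 50000))
#' @seealso [binarize_label()], [affinity_threshold()]
#' @export
transform_ic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("`ic50_nM` must be finite and strictly positive.", call. = FALSE)
  }
  pmin(pmax(1 - log(ic50_nM) / log(50000), 0), 1)
}

#' The binder threshold on the transformed affinity scale
#'
#' The field's conventional binder cut-off is IC50 <= 500 nM; on the
#' transformed scale this is `1 - log(500)/log(50000)`, about 0.4256.
#'
#' @return A single numeric value.
#' @export
affinity_threshold <- function() {
  1 - log(500) / log(50000)
}

#' Binarize a transformed affinity into binder / non-binder
#'
#' Applies the 500 nM binder convention on the transformed scale: a peptide
#' is a binder (1) when its transformed affinity is at least
#' [affinity_threshold()]. Equality is assigned to the binder class, so
#' IC50 = 500 nM exactly counts as binding.
#'
#' @param y Numeric vector of transformed affinities in \[0, 1\].
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_label(transform_ic50(c(499, 501)))
#' @export
binarize_label <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0 | y > 1)) {
    stop("`y` must lie in [0, 1].", call. = FALSE)
  }
  as.integer(y >= affinity_threshold())
}

#' Pad or truncate peptides to a fixed encoded length
#'
#' The interaction-matrix encoder works on a fixed peptide axis of length 20,
#' so peptides are right-padded with [pad_char()] when shorter and truncated
#' when longer. Truncation keeps the N-terminal residues by default
#' (`keep = "n"`); `keep = "c"` keeps the C-terminal end instead. The
#' operation is idempotent and vectorised.
#'
#' @param peptide Character vector of peptide sequences over the alphabet.
#' @param target_len Encoded length (default 20).
#' @param keep Which end survives truncation: `"n"` (default) or `"c"`.
#' @return A tibble with columns `peptide` (normalized, `target_len` chars),
#'   `raw_length` (residue count before padding, capped at `target_len` for
#'   already-padded input).
#' @examples
#' normalize_peptide(c("AAAAAAAAA", strrep("C", 25)))
#' @export
normalize_peptide <- function(peptide, target_len = 20L, keep = c("n", "c")) {
  keep <- match.arg(keep)
  if (length(peptide) == 0L) {
    return(tibble::tibble(peptide = character(), raw_length = integer()))
  }
  if (any(is.na(peptide)) || any(nchar(gsub(pad_char(), "", peptide, fixed = TRUE)) == 0L)) {
    stop("Peptides must be non-empty.", call. = FALSE)
  }
  # strip any existing padding so the operation is idempotent
  stripped <- sub(sprintf("\\%s+$", pad_char()), "", peptide)
  bad <- !is_valid_sequence(stripped)
  if (any(bad)) {
    stop("Peptide(s) contain residues outside the alphabet: ",
         paste(utils::head(stripped[bad], 3), collapse = ", "), call. = FALSE)
  }
  raw_len <- nchar(stripped)
  out <- ifelse(
    raw_len >= target_len,
    if (keep == "n") substr(stripped, 1L, target_len)
    else substr(stripped, pmax(1L, raw_len - target_len + 1L), raw_len),
    paste0(stripped, strrep(pad_char(), pmax(0L, target_len - raw_len)))
  )
  tibble::tibble(peptide = out, raw_length = pmin(raw_len, target_len))
}

#' Read a tabular affinity dataset
#'
#' Expects delimited text with a header naming at least an allele column and
#' a peptide column, plus one of `ic50` (raw nM), `y` (transformed affinity
#' in \[0,1\]) or `label` (binary). Column names are matched
#' case-insensitively with common synonyms (`mhc`/`allele`,
#' `peptide`/`sequence`, `ic50`/`ic50_nm`/`affinity_nm`,
#' `y`/`affinity`/`meas`, `label`/`binder`). When `ic50` is present, `y` is
#' computed with [transform_ic50()]; when both are present they must agree.
#' Residues outside the alphabet are replaced by `X` with a warning
#' reporting the substitution count.
#'
#' @param path File path to a CSV/TSV file. The delimiter is sniffed from
#'   the header line unless `delim` is given.
#' @param delim Optional explicit delimiter.
#' @return A tibble with columns `allele`, `peptide`, `y` and, when
#'   available, `ic50_nM` and `binary_label`. The number of residue
#'   substitutions is attached as attribute `n_sanitized`.
#' @export
read_affinity_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("Cannot read affinity table: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  i_allele <- pick(c("allele", "mhc", "molecule"))
  i_pep    <- pick(c("peptide", "sequence", "pep"))
  i_ic50   <- pick(c("ic50", "ic50_nm", "affinity_nm"))
  i_y      <- pick(c("y", "affinity", "meas", "measurement"))
  i_lab    <- pick(c("label", "binary_label", "binder"))
  if (is.na(i_allele) || is.na(i_pep) || (is.na(i_ic50) && is.na(i_y) && is.na(i_lab))) {
    stop("Affinity table must name allele, peptide and one of ic50/y/label columns; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  san <- sanitize_residues(as.character(df[[i_pep]]))
  if (san$n_replaced > 0) {
    warning(sprintf("%d residue(s) outside the alphabet replaced by X.", san$n_replaced),
            call. = FALSE)
  }
  out <- tibble::tibble(
    allele = as.character(df[[i_allele]]),
    peptide = san$seq
  )
  if (!is.na(i_ic50)) {
    out$ic50_nM <- as.numeric(df[[i_ic50]])
    out$y <- transform_ic50(out$ic50_nM)
    if (!is.na(i_y)) {
      given <- as.numeric(df[[i_y]])
      if (any(abs(given - out$y) > 1e-9)) {
        stop("Columns ic50 and y disagree beyond 1e-9.", call. = FALSE)
      }
    }
  } else if (!is.na(i_y)) {
    out$y <- as.numeric(df[[i_y]])
    if (any(!is.finite(out$y)) || any(out$y < 0 | out$y > 1)) {
      stop("Transformed affinities must lie in [0, 1].", call. = FALSE)
    }
  }
  if (!is.na(i_lab)) {
    out$binary_label <- as.integer(df[[i_lab]])
    if (any(!out$binary_label %in% c(0L, 1L))) {
      stop("Binary labels must be 0 or 1.", call. = FALSE)
    }
  } else if (!is.null(out$y)) {
    out$binary_label <- binarize_label(out$y)
  }
  if (any(out$allele == "" | is.na(out$allele))) {
    stop("Empty allele names are not allowed.", call. = FALSE)
  }
  attr(out, "n_sanitized") <- san$n_replaced
  out
}

#' Write an affinity dataset
#'
#' Inverse of [read_affinity_table()]; writing then re-reading reproduces
#' `allele`, `peptide` and `y` exactly.
#'
#' @param data Tibble with at least `allele`, `peptide`, `y`.
#' @param path Output path.
#' @param delim Delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(data, path, delim = "\t") {
  keep <- intersect(c("allele", "peptide", "y", "ic50_nM", "binary_label"), names(data))
  readr::write_delim(data[keep], path, delim = delim)
  invisible(path)
}

#' Read an MHC pseudo-sequence table
#'
#' A pseudo-sequence is a fixed selection of 34 binding-groove residues (15
#' from the alpha chain, 19 from the beta chain for class II) that serves as
#' a compact allele representation for pan-specific prediction. The table is
#' two-column delimited text: allele name, 34-mer.
#'
#' @param path File path.
#' @param delim Optional delimiter (sniffed when `NULL`).
#' @return A tibble with columns `allele` and `pseudo`.
#' @export
read_pseudosequence_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("Cannot read pseudo-sequence table: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  if (ncol(df) < 2) stop("Pseudo-sequence table needs two columns (allele, pseudo).", call. = FALSE)
  out <- tibble::tibble(allele = as.character(df[[1]]),
                        pseudo = toupper(as.character(df[[2]])))
  validate_pseudo_map(out)
}

#' @keywords internal
validate_pseudo_map <- function(out) {
  if (any(out$allele == "" | is.na(out$allele))) {
    stop("Empty allele names are not allowed.", call. = FALSE)
  }
  dup <- out$allele[duplicated(out$allele)]
  if (length(dup)) {
    stop("Duplicate allele name(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_len <- nchar(out$pseudo) != 34L
  if (any(bad_len)) {
    stop("Pseudo-sequence for allele(s) ", paste(out$allele[bad_len], collapse = ", "),
         " is not 34 residues long.", call. = FALSE)
  }
  bad_res <- !is_valid_sequence(out$pseudo)
  if (any(bad_res)) {
    stop("Pseudo-sequence for allele(s) ", paste(out$allele[bad_res], collapse = ", "),
         " contains residues outside the alphabet.", call. = FALSE)
  }
  out
}

#' Write an MHC pseudo-sequence table
#' @param data Tibble with columns `allele`, `pseudo`.
#' @param path Output path.
#' @param delim Delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_pseudosequence_table <- function(data, path, delim = "\t") {
  validate_pseudo_map(data[c("allele", "pseudo")])
  readr::write_delim(data[c("allele", "pseudo")], path, delim = delim)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and residues outside the alphabet are replaced
#' by `X` (e.g. selenocysteine `U`).
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("Cannot read FASTA: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("Not a FASTA file (", conditionMessage(e), "): ",
                         path, call. = FALSE)
                  })
  if (length(set) == 0) {
    stop("Not a FASTA file (no records): ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  san <- sanitize_residues(as.character(set))
  tibble::tibble(id = unname(ids), seq = unname(san$seq))
}

#' Sniff the delimiter of a delimited text file
#' @keywords internal
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))))
  if (all(counts == 0)) return("\t")
  names(counts)[which.max(counts)]
}
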