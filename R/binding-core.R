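#' Locate the binding core of a peptide by sliding a 9-mer window
#'
#' The 9-residue segment seated in the MHC-II groove dominates binding, so
#' the core is localised by scoring every 9-mer window of the peptide and
#' taking the argmax; ties break to the smallest offset. By default each
#' window is scored as a standalone peptide (padded to the encoded length
#' of 20); `context = "masked"` instead scores the full-length peptide
#' with all residues outside the window replaced by `X`, which retains the
#' window's position within the peptide.
#'
#' @param model An `affinity_predictor` or `rpe_ensemble`.
#' @param allele Allele name resolvable in the model's pseudo-sequence map.
#' @param peptide Peptide of at least 9 residues.
#' @param context `"isolated"` (default) or `"masked"`.
#' @return An object of class `core_prediction`: list with `peptide`,
#'   `allele`, `core` (9-mer), `offset` (0-based), `window_scores`.
#' @export
predict_core <- function(model, allele, peptide,
                         context = c("isolated", "masked")) {
  context <- match.arg(context)
  peptide <- toupper(peptide)
  if (!is_valid_sequence(peptide)) {
    stop("Peptide contains residues outside the alphabet.", call. = FALSE)
  }
  len <- nchar(peptide)
  if (len < 9L) stop("Peptide shorter than the 9-residue core.", call. = FALSE)
  offsets <- 0:(len - 9L)
  windows <- substring(peptide, offsets + 1L, offsets + 9L)
  query <- if (context == "isolated") {
    tibble::tibble(allele = allele, peptide = windows)
  } else {
    masked <- vapply(offsets, function(o) {
      paste0(strrep("X", o), substr(peptide, o + 1L, o + 9L),
             strrep("X", len - o - 9L))
    }, character(1))
    tibble::tibble(allele = allele, peptide = masked)
  }
  scores <- predict(model, query)$.pred
  best <- which.max(scores)  # which.max takes the first maximum: smallest offset
  structure(
    list(peptide = peptide, allele = allele,
         core = windows[best], offset = offsets[best],
         window_scores = scores),
    class = "core_prediction"
  )
}

#' @export
print.core_prediction <- function(x, ...) {
  cat("<core_prediction> ", x$allele, " ", x$peptide, "\n  core ", x$core,
      " at offset ", x$offset, " (", length(x$window_scores), " windows)\n",
      sep = "")
  invisible(x)
}

#' Build a binding-motif frequency matrix from random peptides
#'
#' Emulates motif extraction from a trained predictor: draw `n_peptides`
#' random peptides of length `peptide_len` (uniform over the 20 standard
#' residues, or substrings of user-supplied background proteins), score
#' them all, keep the top `top_frac` fraction by predicted affinity,
#' localise each survivor's 9-mer core with [predict_core()], and count
#' residues per core position. The convention mirrored here is the top 1%
#' of 100,000 random 15-mers.
#'
#' @param model An `affinity_predictor` or `rpe_ensemble`.
#' @param allele Allele to profile.
#' @param n_peptides Number of random peptides (default 100000).
#' @param peptide_len Their length (default 15).
#' @param top_frac Fraction kept (default 0.01); `floor(n_peptides * top_frac)`
#'   peptides contribute.
#' @param background Optional tibble from [read_fasta()]; when given,
#'   peptides are random substrings of its sequences instead of uniform
#'   residue draws.
#' @param seed Sampling seed; the whole construction is reproducible.
#' @param context Window-scoring mode passed to [predict_core()].
#' @return An object of class `motif_matrix`: list with `allele`, `counts`
#'   (9 x 21 integer matrix, columns the alphabet), `frequencies`
#'   (rows sum to 1), `n_contributing`.
#' @export
build_motif <- function(model, allele, n_peptides = 100000L, peptide_len = 15L,
                        top_frac = 0.01, background = NULL, seed = 1L,
                        context = c("isolated", "masked")) {
  context <- match.arg(context)
  stopifnot(top_frac > 0, top_frac <= 1, peptide_len >= 9L)
  n_keep <- floor(n_peptides * top_frac)
  if (n_keep < 1L) {
    stop("`n_peptides` must be at least 1 / top_frac.", call. = FALSE)
  }
  set.seed(seed)
  peptides <- sample_background_peptides(n_peptides, peptide_len, background)
  scored <- predict(model, tibble::tibble(allele = allele, peptide = peptides))
  top <- scored[order(scored$.pred, decreasing = TRUE)[seq_len(n_keep)], ]
  ab <- amino_alphabet()
  counts <- matrix(0L, nrow = 9L, ncol = length(ab),
                   dimnames = list(paste0("p", 1:9), ab))
  for (pep in top$peptide) {
    core <- predict_core(model, allele, pep, context = context)$core
    idx <- aa_index(core)
    for (p in 1:9) counts[p, idx[p]] <- counts[p, idx[p]] + 1L
  }
  structure(
    list(allele = allele, counts = counts,
         frequencies = counts / rowSums(counts),
         n_contributing = n_keep),
    class = "motif_matrix"
  )
}

# uniform 20-residue peptides, or substrings of background proteins
sample_background_peptides <- function(n, len, background = NULL) {
  if (is.null(background)) {
    std <- amino_alphabet()[1:20]
    mat <- matrix(sample(std, n * len, replace = TRUE), nrow = n)
    return(apply(mat, 1, paste, collapse = ""))
  }
  seqs <- background$seq[nchar(background$seq) >= len]
  if (length(seqs) == 0L) {
    stop("No background sequence is at least ", len, " residues long.",
         call. = FALSE)
  }
  src <- sample(seq_along(seqs), n, replace = TRUE)
  starts <- vapply(src, function(i) sample.int(nchar(seqs[i]) - len + 1L, 1L),
                   integer(1))
  substring(seqs[src], starts, starts + len - 1L)
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix> ", x$allele, ", ", x$n_contributing,
      " contributing cores\n", sep = "")
  ic <- information_content(x)
  cat("  information content: ",
      paste(sprintf("%.2f", ic), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-position information content of a motif
#'
#' `log2(20) - H(p)` per core position, computed over the 20 standard
#' residues after renormalising any `X` counts away (logo alphabets are
#' the standard residues). A uniform position scores 0; a single-residue
#' position scores `log2(20)` (about 4.32). Positions with zero standard
#' residue counts are `NA`.
#'
#' @param motif A `motif_matrix`.
#' @return Numeric vector of length 9.
#' @export
information_content <- function(motif) {
  stopifnot(inherits(motif, "motif_matrix"))
  std <- motif$counts[, 1:20, drop = FALSE]
  apply(std, 1, function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    p <- cnt / tot
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}

#' Export a motif as a position-frequency-matrix text file
#'
#' Rows are core positions 1..9, columns the 21 alphabet symbols; a
#' commented header records the allele, contributing-core count and
#' alphabet so standard logo tools can consume the file.
#'
#' @param motif A `motif_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# rpemhc position frequency matrix v1",
    paste0("# allele: ", motif$allele),
    paste0("# n_contributing: ", motif$n_contributing),
    paste0("# columns: ", paste(colnames(motif$counts), collapse = " "))
  ), con)
  utils::write.table(format(motif$frequencies, digits = 6), con,
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare predicted core offsets against references
#'
#' Given reference core offsets (e.g. from solved structures), reports the
#' exact-match count and the histogram of offset errors.
#'
#' @param predictions A list of `core_prediction` objects.
#' @param reference_offsets Integer vector of the same length (0-based).
#' @return A list with `n_exact`, `n_total`, and `offset_error` (tibble of
#'   signed error counts).
#' @export
compare_core_offsets <- function(predictions, reference_offsets) {
  stopifnot(length(predictions) == length(reference_offsets))
  pred_off <- vapply(predictions, function(p) p$offset, integer(1))
  err <- pred_off - reference_offsets
  list(
    n_exact = sum(err == 0L),
    n_total = length(err),
    offset_error = tibble::tibble(error = as.integer(names(table(err))),
                                  count = as.integer(table(err)))
  )
}
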