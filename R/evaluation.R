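#' Compute the evaluation metric suite on a prediction table
#'
#' Computes AUC (rank statistic with midranks for ties), PRC (average
#' precision), PCC (Pearson correlation of continuous labels and scores),
#' and PPV / F1 / sensitivity from the confusion matrix after binarizing
#' predictions at the same 500 nM threshold used for labels. Metrics whose
#' preconditions fail are reported as `NA` with a reason code rather than
#' as zero: AUC/PRC need both classes, PCC needs at least two rows and a
#' continuous `y_true` with nonzero variance.
#'
#' @param table Tibble with a score column `.pred` and either `binary_true`
#'   (0/1) or `y_true` (transformed affinity, binarized internally) or both.
#' @param threshold Score threshold for the confusion-matrix metrics
#'   (default [affinity_threshold()]).
#' @return A one-row tibble with columns `n`, `n_binders`, `auc`, `prc`,
#'   `pcc`, `ppv`, `f1`, `sensitivity`, `reason` (NA or a short code).
#' @export
compute_metrics <- function(table, threshold = affinity_threshold()) {
  score <- table$.pred
  y_true <- if ("y_true" %in% names(table)) table[["y_true"]] else table[["y"]]
  label <- if ("binary_true" %in% names(table)) as.integer(table$binary_true)
           else binarize_label(y_true)
  n <- length(score)
  reasons <- character(0)

  auc <- prc <- NA_real_
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos > 0 && n_neg > 0) {
    auc <- auc_rank(score, label)
    prc <- average_precision(score, label)
  } else {
    reasons <- c(reasons, "single_class")
  }

  pcc <- NA_real_
  if (!is.null(y_true) && n >= 2L) {
    if (stats::sd(y_true) > 0 && stats::sd(score) > 0) {
      pcc <- stats::cor(y_true, score)
    } else {
      reasons <- c(reasons, "constant_input")
    }
  } else if (is.null(y_true)) {
    reasons <- c(reasons, "no_continuous_labels")
  } else {
    reasons <- c(reasons, "too_few_rows")
  }

  pred_bin <- as.integer(score >= threshold)
  tp <- sum(pred_bin == 1L & label == 1L)
  fp <- sum(pred_bin == 1L & label == 0L)
  fn <- sum(pred_bin == 0L & label == 1L)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_

  tibble::tibble(
    n = n, n_binders = n_pos, auc = auc, prc = prc, pcc = pcc,
    ppv = ppv, f1 = f1, sensitivity = sens,
    reason = if (length(reasons)) paste(unique(reasons), collapse = ";") else NA_character_
  )
}

# Mann-Whitney AUC via midranks; ties between classes count one half.
auc_rank <- function(score, label) {
  r <- rank(score, ties.method = "average")
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  (sum(r[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision: precision at each positive, descending score order.
# Ties are handled by treating tied blocks as a single cut (precision of
# the whole block assigned to its positives), so the value is invariant to
# the ordering within ties.
average_precision <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  l <- label[o]
  n_pos <- sum(l == 1L)
  blocks <- cumsum(!duplicated(s))
  tp_cum <- cumsum(l == 1L)
  n_cum <- seq_along(l)
  last_of_block <- !duplicated(blocks, fromLast = TRUE)
  tp_b <- tp_cum[last_of_block]
  n_b <- n_cum[last_of_block]
  pos_in_block <- diff(c(0, tp_b))
  sum((tp_b / n_b) * pos_in_block) / n_pos
}

#' Per-molecule evaluation report with averaging filters
#'
#' Groups a prediction table by allele, computes the metric suite per
#' allele, and reports which alleles enter the macro-average. An allele is
#' included when it has strictly more than `min_peptides` peptides and at
#' least `min_binders` binders (the customary reporting filter; e.g. more
#' than 40 peptides and at least 3 binders on the large cross-validation
#' benchmark, more than 20 on smaller independent sets). The summary
#' reports the macro-average and sample standard deviation over included
#' alleles, plus pooled-"All" metrics over the whole table.
#'
#' @param table Prediction tibble with `allele`, `.pred` and labels as in
#'   [compute_metrics()].
#' @param min_peptides Strict lower bound on per-allele peptide count.
#' @param min_binders Minimum binder count (default 3).
#' @return A list with `molecules` (per-allele tibble, flag
#'   `included_in_average`), `average` (macro mean and sd per metric over
#'   included alleles, with `n_molecules`), and `all` (pooled metrics).
#' @export
per_molecule_report <- function(table, min_peptides = 40L, min_binders = 3L) {
  stopifnot("allele" %in% names(table))
  mols <- table |>
    dplyr::group_by(.data$allele) |>
    dplyr::group_modify(~ compute_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(included_in_average =
                    .data$n > min_peptides & .data$n_binders >= min_binders)
  metric_cols <- c("auc", "prc", "pcc", "ppv", "f1", "sensitivity")
  inc <- mols[mols$included_in_average, , drop = FALSE]
  avg <- tibble::tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(m) mean(inc[[m]], na.rm = TRUE),
                         numeric(1))),
    sd = unname(vapply(metric_cols, function(m) stats::sd(inc[[m]], na.rm = TRUE),
                       numeric(1))),
    n_molecules = nrow(inc)
  )
  list(molecules = mols, average = avg, all = compute_metrics(table))
}

#' Annotate an epitope benchmark case
#'
#' Builds the candidate set for epitope ranking within a source protein:
#' every overlapping substring of the protein with the epitope's length is
#' a candidate; candidates identical to the epitope string are positives
#' (all occurrences), the rest negatives.
#'
#' @param epitope Epitope sequence (must occur in `source_protein`).
#' @param source_protein Protein sequence over the alphabet.
#' @param allele Allele name attached to every row.
#' @return Tibble with `allele`, `peptide`, `offset` (0-based) and
#'   `binary_true`.
#' @export
annotate_epitope_case <- function(epitope, source_protein, allele) {
  epitope <- toupper(epitope)
  source_protein <- toupper(source_protein)
  le <- nchar(epitope)
  lp <- nchar(source_protein)
  if (le > lp) stop("Epitope longer than its source protein.", call. = FALSE)
  if (!is_valid_sequence(epitope) || !is_valid_sequence(source_protein)) {
    stop("Sequences contain residues outside the alphabet.", call. = FALSE)
  }
  starts <- seq_len(lp - le + 1L)
  peptides <- substring(source_protein, starts, starts + le - 1L)
  if (!any(peptides == epitope)) {
    stop("Epitope does not occur in the source protein.", call. = FALSE)
  }
  tibble::tibble(allele = allele, peptide = peptides, offset = starts - 1L,
                 binary_true = as.integer(peptides == epitope))
}

#' Frank value of one scored epitope case
#'
#' The fraction of candidate peptides scored strictly higher than the
#' positive epitope, out of all candidates except the epitope itself:
#' 0 means the epitope ranks first (perfect), 0.5 means as many candidates
#' score above as below. Ties with the epitope do not count against it.
#' When the epitope occurs several times in the protein (several positive
#' rows), the best-scoring positive is the reference and the other
#' positives are excluded from the comparison set.
#'
#' @param case_table Tibble with `.pred` and `binary_true`, at least one
#'   positive row.
#' @return A single number in \[0, 1\].
#' @export
frank <- function(case_table) {
  pos <- which(case_table$binary_true == 1L)
  if (length(pos) == 0L) stop("Case has no positive row.", call. = FALSE)
  ref <- max(case_table$.pred[pos])
  neg_scores <- case_table$.pred[-pos]
  if (length(neg_scores) == 0L) return(0)
  sum(neg_scores > ref) / length(neg_scores)
}

#' Evaluate a whole epitope benchmark
#'
#' Scores each (epitope, source protein, allele) case with a model and
#' reports per-case Frank and AUC.
#'
#' @param model An `affinity_predictor` or `rpe_ensemble`.
#' @param cases Tibble with columns `epitope`, `source_protein`, `allele`.
#' @return Tibble with one row per case: `allele`, `epitope`, `n_candidates`,
#'   `frank`, `auc`.
#' @export
evaluate_epitope_benchmark <- function(model, cases) {
  purrr::pmap_dfr(cases[c("epitope", "source_protein", "allele")],
    function(epitope, source_protein, allele) {
      tab <- annotate_epitope_case(epitope, source_protein, allele)
      tab <- predict(model, tab)
      tibble::tibble(
        allele = allele, epitope = epitope, n_candidates = nrow(tab),
        frank = frank(tab),
        auc = compute_metrics(tab)$auc
      )
    })
}
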