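#' Build an allele-stratified k-fold split plan
#'
#' Records are shuffled within allele (alleles themselves in shuffled
#' order) and dealt round-robin over the k folds, so global fold sizes
#' differ by at most one and every allele with at least k records has
#' per-fold counts differing by at most one.
#'
#' @param data Tibble with at least an `allele` column.
#' @param k Number of folds (default 5).
#' @param seed Shuffling seed.
#' @return An object of class `split_plan`: a list with `assignments`
#'   (tibble `row`, `allele`, `fold`), `k`, `protocol`.
#' @export
make_kfold <- function(data, k = 5L, seed = 1L) {
  n <- nrow(data)
  if (k < 2L) stop("`k` must be at least 2.", call. = FALSE)
  if (n < k) stop("Dataset smaller than the number of folds.", call. = FALSE)
  set.seed(seed)
  alleles <- unique(data$allele)
  allele_order <- sample(alleles)
  row_order <- unlist(lapply(allele_order, function(a) {
    rows <- which(data$allele == a)
    if (length(rows) > 1L) sample(rows) else rows
  }), use.names = FALSE)
  fold <- integer(n)
  fold[row_order] <- (seq_len(n) - 1L) %% k + 1L
  structure(list(
    assignments = tibble::tibble(row = seq_len(n), allele = data$allele,
                                 fold = fold),
    k = as.integer(k), protocol = "kfold", held_out_allele = NULL
  ), class = "split_plan")
}

#' Derive a leave-one-molecule-out plan from a k-fold plan
#'
#' LOMO probes generalisation to alleles absent from training: in round r
#' the training portion is the other k-1 folds with every record of the
#' held-out allele removed, and the test portion is fold r restricted to
#' the held-out allele. The union of test portions over rounds is exactly
#' that allele's records, each appearing once; out-of-fold predictions are
#' then combined into one per-allele result.
#'
#' @param data The tibble the base plan was built on.
#' @param allele The allele to hold out.
#' @param base_kfold A [make_kfold()] plan for `data`.
#' @return A `split_plan` with `protocol = "lomo"`.
#' @export
make_lomo <- function(data, allele, base_kfold) {
  stopifnot(inherits(base_kfold, "split_plan"))
  if (!allele %in% data$allele) {
    stop("Allele '", allele, "' not present in the dataset.", call. = FALSE)
  }
  plan <- base_kfold
  plan$protocol <- "lomo"
  plan$held_out_allele <- allele
  plan
}

#' Row indices of a plan's training portion for one round
#' @param plan A `split_plan`.
#' @param round Fold index in 1..k.
#' @return Integer row indices.
#' @export
split_train_indices <- function(plan, round) {
  a <- plan$assignments
  keep <- a$fold != round
  if (identical(plan$protocol, "lomo")) keep <- keep & a$allele != plan$held_out_allele
  a$row[keep]
}

#' Row indices of a plan's test portion for one round
#' @param plan A `split_plan`.
#' @param round Fold index in 1..k.
#' @return Integer row indices.
#' @export
split_test_indices <- function(plan, round) {
  a <- plan$assignments
  keep <- a$fold == round
  if (identical(plan$protocol, "lomo")) keep <- keep & a$allele == plan$held_out_allele
  a$row[keep]
}

#' Out-of-fold predictions under k-fold cross-validation
#'
#' Trains one model per fold on the other folds and predicts the held-out
#' fold; the combined out-of-fold predictions cover every record once.
#'
#' @param data Tibble with `allele`, `peptide`, `y`.
#' @param pseudo_map Pseudo-sequence map.
#' @param config,spec Model and training settings.
#' @param k,seed Fold count and shuffling seed.
#' @param n_members Ensemble members per fold (default 1).
#' @param verbose Print progress.
#' @return `data` with `.pred` and `fold` columns.
#' @export
crossval_predict <- function(data, pseudo_map, config = model_config(),
                             spec = train_spec(), k = 5L, seed = 1L,
                             n_members = 1L, verbose = FALSE) {
  plan <- make_kfold(data, k, seed)
  out <- data
  out$.pred <- NA_real_
  out$fold <- plan$assignments$fold
  for (r in seq_len(k)) {
    tr <- split_train_indices(plan, r)
    te <- split_test_indices(plan, r)
    model <- if (n_members > 1L) {
      train_ensemble(data[tr, ], pseudo_map, config, spec, n_members)
    } else {
      fit_affinity_model(data[tr, ], pseudo_map, config, spec)
    }
    out$.pred[te] <- predict(model, data[te, ])$.pred
    if (verbose) message("fold ", r, "/", k, " done")
  }
  tibble::as_tibble(out)
}

#' Out-of-fold predictions under leave-one-molecule-out
#'
#' For each requested allele, repeats the k-fold rounds with that allele's
#' records removed from every training portion, and collects its
#' out-of-fold predictions.
#'
#' @param data Tibble with `allele`, `peptide`, `y`.
#' @param pseudo_map Pseudo-sequence map.
#' @param alleles Alleles to hold out (default: all in `data`).
#' @param config,spec Model and training settings.
#' @param k,seed Fold count and shuffling seed.
#' @param verbose Print progress.
#' @return Tibble of the held-out alleles' rows with `.pred` and `fold`.
#' @export
lomo_predict <- function(data, pseudo_map, alleles = unique(data$allele),
                         config = model_config(), spec = train_spec(),
                         k = 5L, seed = 1L, verbose = FALSE) {
  base <- make_kfold(data, k, seed)
  res <- list()
  for (a in alleles) {
    plan <- make_lomo(data, a, base)
    part <- data[data$allele == a, , drop = FALSE]
    preds <- rep(NA_real_, nrow(data))
    folds <- rep(NA_integer_, nrow(data))
    for (r in seq_len(k)) {
      tr <- split_train_indices(plan, r)
      te <- split_test_indices(plan, r)
      if (length(te) == 0L) next
      model <- fit_affinity_model(data[tr, ], pseudo_map, config, spec)
      preds[te] <- predict(model, data[te, ])$.pred
      folds[te] <- r
      if (verbose) message("lomo ", a, " round ", r, "/", k, " done")
    }
    rows <- which(data$allele == a)
    part$.pred <- preds[rows]
    part$fold <- folds[rows]
    res[[a]] <- part
  }
  dplyr::bind_rows(res)
}
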