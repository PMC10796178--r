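#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted predictor's training history
#'
#' @param x An `affinity_predictor`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss` (empty for an
#'   untrained predictor).
#' @export
tidy.affinity_predictor <- function(x, ...) {
  if (is.null(x$log)) {
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric()))
  }
  x$log
}

#' One-row summary of a fitted predictor
#'
#' @param x An `affinity_predictor`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs trained, final train loss,
#'   best validation loss and the seed.
#' @export
glance.affinity_predictor <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x$config),
    n_alleles = nrow(x$pseudo_map),
    epochs_trained = if (is.null(x$log)) 0L else max(x$log$epoch),
    train_loss = if (is.null(x$log)) NA_real_ else
      x$log$train_loss[nrow(x$log)],
    best_val_loss = if (is.null(x$log) || all(is.na(x$log$val_loss))) NA_real_
      else min(x$log$val_loss, na.rm = TRUE),
    seed = x$seed
  )
}

#' Per-member summaries of an ensemble
#'
#' @param x An `rpe_ensemble`.
#' @param ... Unused.
#' @return One [glance.affinity_predictor()] row per member with a
#'   `member` index column.
#' @export
tidy.rpe_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$members), function(k) {
    dplyr::mutate(glance(x$members[[k]]), member = k, .before = 1)
  }))
}

#' One-row summary of an ensemble
#' @param x An `rpe_ensemble`.
#' @param ... Unused.
#' @return Tibble with member count and mean best validation loss.
#' @export
glance.rpe_ensemble <- function(x, ...) {
  members <- tidy(x)
  tibble::tibble(
    n_members = length(x$members),
    n_params = members$n_params[1],
    mean_best_val_loss = mean(members$best_val_loss)
  )
}

#' Long-format view of a motif matrix
#'
#' @param x A `motif_matrix`.
#' @param ... Unused.
#' @return Tibble with `position`, `residue`, `count`, `frequency`.
#' @export
tidy.motif_matrix <- function(x, ...) {
  tibble::tibble(
    position = rep(1:9, times = ncol(x$counts)),
    residue = rep(colnames(x$counts), each = 9),
    count = as.vector(x$counts),
    frequency = as.vector(x$frequencies)
  )
}

#' One-row summary of a motif matrix
#' @param x A `motif_matrix`.
#' @param ... Unused.
#' @return Tibble with the allele, contributing-core count, and the four
#'   positions of highest information content.
#' @export
glance.motif_matrix <- function(x, ...) {
  ic <- information_content(x)
  tibble::tibble(
    allele = x$allele,
    n_contributing = x$n_contributing,
    mean_ic = mean(ic, na.rm = TRUE),
    top_positions = paste(sort(order(ic, decreasing = TRUE)[1:4]),
                          collapse = ",")
  )
}

#' Window scores of a core prediction as a tibble
#'
#' @param x A `core_prediction`.
#' @param ... Unused.
#' @return Tibble with `offset`, `window`, `score`, `is_core`.
#' @export
tidy.core_prediction <- function(x, ...) {
  offsets <- seq_along(x$window_scores) - 1L
  tibble::tibble(
    offset = offsets,
    window = substring(x$peptide, offsets + 1L, offsets + 9L),
    score = x$window_scores,
    is_core = offsets == x$offset
  )
}
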