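#' Create an (untrained) affinity predictor
#'
#' Bundles freshly initialised parameters with their configuration, the
#' pair-code vocabulary version and the pseudo-sequence map used to resolve
#' allele names. Training (see [fit_affinity_model()]) returns the same
#' structure with learned parameters and a training log.
#'
#' @param config An [model_config()] object.
#' @param pseudo_map Tibble with columns `allele`, `pseudo`.
#' @param seed Seed for parameter initialisation.
#' @return An object of class `affinity_predictor`.
#' @export
new_affinity_predictor <- function(config = model_config(), pseudo_map, seed = 1L) {
  stopifnot(inherits(config, "rpe_config"))
  pseudo_map <- validate_pseudo_map(pseudo_map[c("allele", "pseudo")])
  structure(
    list(params = init_params(config, seed), config = config,
         pseudo_map = pseudo_map, vocab_version = vocabulary_version(),
         alphabet = paste(amino_alphabet(), collapse = ""), seed = seed),
    class = "affinity_predictor"
  )
}

#' @export
print.affinity_predictor <- function(x, ...) {
  cat("<affinity_predictor> ", format(n_params(x$config), big.mark = ","),
      " parameters, ", nrow(x$pseudo_map), " allele(s), vocabulary ",
      x$vocab_version, "\n", sep = "")
  if (!is.null(x$log)) {
    cat("  trained ", max(x$log$epoch), " epoch(s), best validation MSE ",
        signif(min(x$log$val_loss), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Predict binding affinities
#'
#' Scores (allele, peptide) rows with the network in inference mode
#' (no dropout). Predictions are strictly inside (0, 1) by the sigmoid
#' head. Batch composition does not affect results beyond floating-point
#' tolerance.
#'
#' @param object An `affinity_predictor`.
#' @param newdata Tibble with columns `allele` and `peptide`.
#' @param batch_size Rows scored per forward pass.
#' @param ... Unused.
#' @return The input tibble with a `.pred` column appended.
#' @export
predict.affinity_predictor <- function(object, newdata, batch_size = 256L, ...) {
  if (nrow(newdata) == 0L) {
    newdata$.pred <- numeric(0)
    return(tibble::as_tibble(newdata))
  }
  codes <- encode_dataset(newdata, object$pseudo_map)
  newdata$.pred <- forward_codes(object$params, object$config, codes, batch_size)
  tibble::as_tibble(newdata)
}

# chunked inference on an encoded matrix
forward_codes <- function(params, config, codes, batch_size = 256L) {
  cfg <- as_cpp_config(config)
  n <- nrow(codes)
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx] <- rpe_net_run(params, codes[idx, , drop = FALSE], cfg,
                            NULL, FALSE, 0L)$yhat
  }
  out
}

#' Save a predictor checkpoint
#'
#' The checkpoint is self-describing: it embeds the configuration, the
#' alphabet order, the pair-code formula version and the pseudo-sequence
#' map alongside the parameters. [load_checkpoint()] refuses files whose
#' vocabulary version differs from the package's.
#'
#' @param object An `affinity_predictor` or `rpe_ensemble`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("affinity_predictor", "rpe_ensemble")))
  saveRDS(object, path)
  invisible(path)
}

#' Load a predictor checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The stored object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  vv <- if (inherits(obj, "rpe_ensemble")) obj$members[[1]]$vocab_version else obj$vocab_version
  if (!identical(vv, vocabulary_version())) {
    stop("Checkpoint vocabulary version '", vv,
         "' does not match the package's '", vocabulary_version(), "'.",
         call. = FALSE)
  }
  obj
}
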