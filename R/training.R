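#' Mean squared error
#'
#' The training objective: the mean over samples of the squared difference
#' between measured and predicted transformed affinity.
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1L) {
    stop("`y` and `y_hat` must have equal length >= 1.", call. = FALSE)
  }
  mean((y - y_hat)^2)
}

#' Training specification
#'
#' Hyperparameters of a single training run. Defaults: Adam with learning
#' rate 1e-3, batches of 128, up to 100 epochs with early stopping after
#' `patience` epochs without validation improvement on a 10% validation
#' split carved from the training data. The seed drives every source of
#' randomness (initialisation, shuffling, dropout, validation split), so a
#' run is fully reproducible from (data, config, spec).
#'
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is provided.
#' @param seed Integer seed.
#' @param patience Early-stopping patience in epochs; `Inf` disables.
#' @param validation_fraction Fraction of training rows held out for model
#'   selection; 0 disables (the final epoch's parameters are returned).
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(epochs = 100L, batch_size = 128L, learning_rate = 1e-3,
                       optimizer = "adam", seed = 1L, patience = 10L,
                       validation_fraction = 0.1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            identical(optimizer, "adam"),
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), patience = patience,
                 validation_fraction = validation_fraction),
            class = "train_spec")
}

#' Fit one affinity predictor
#'
#' Trains the network by minibatch Adam on the MSE objective. The returned
#' predictor carries the parameter state with the best validation MSE (or
#' the final state when no validation split is used) and a per-epoch log of
#' train/validation loss.
#'
#' @param data Tibble with columns `allele`, `peptide`, `y`.
#' @param pseudo_map Tibble with columns `allele`, `pseudo` covering every
#'   allele in `data`.
#' @param config An [model_config()].
#' @param spec A [train_spec()].
#' @param verbose Print per-epoch losses.
#' @return An `affinity_predictor` with elements `log` (tibble of `epoch`,
#'   `train_loss`, `val_loss`) and `spec` added.
#' @export
fit_affinity_model <- function(data, pseudo_map, config = model_config(),
                               spec = train_spec(), verbose = FALSE) {
  if (nrow(data) == 0L) stop("Training data is empty.", call. = FALSE)
  if (any(!is.finite(data$y)) || any(data$y < 0 | data$y > 1)) {
    stop("Training labels must lie in [0, 1].", call. = FALSE)
  }
  codes <- encode_dataset(data, pseudo_map)
  y <- data$y
  n <- nrow(codes)
  set.seed(spec$seed)
  n_val <- floor(spec$validation_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("No training rows left after validation split.", call. = FALSE)

  params <- init_params(config, seed = spec$seed)
  opt <- adam_state(params)
  cfg <- as_cpp_config(config)

  best_val <- Inf
  best_params <- params
  stale <- 0L
  log <- vector("list", spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    order_idx <- tr_idx[sample.int(length(tr_idx))]
    batch_starts <- seq(1L, length(order_idx), by = spec$batch_size)
    batch_losses <- numeric(length(batch_starts))
    for (bi in seq_along(batch_starts)) {
      idx <- order_idx[batch_starts[bi]:min(batch_starts[bi] + spec$batch_size - 1L,
                                            length(order_idx))]
      res <- rpe_net_run(params, codes[idx, , drop = FALSE], cfg, y[idx],
                         TRUE, sample.int(.Machine$integer.max, 1L))
      if (!is.finite(res$loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d (learning rate %g); aborting.",
                     epoch, spec$learning_rate), call. = FALSE)
      }
      batch_losses[bi] <- res$loss
      params <- adam_step(params, res$grads, opt, spec$learning_rate)
    }
    val_loss <- if (n_val > 0) {
      mse_loss(y[val_idx], forward_codes(params, config,
                                         codes[val_idx, , drop = FALSE]))
    } else NA_real_
    log[[epoch]] <- tibble::tibble(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %s", epoch,
                      mean(batch_losses),
                      ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
    if (n_val > 0) {
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= spec$patience) break
      }
    }
  }
  out <- new_affinity_predictor(config, pseudo_map, seed = spec$seed)
  out$params <- if (n_val > 0) best_params else params
  out$log <- dplyr::bind_rows(log)
  out$spec <- spec
  out
}

# Adam optimiser state and update (bias-corrected); the pad embedding row
# is re-frozen after every step.
adam_state <- function(params) {
  env <- new.env(parent = emptyenv())
  env$m <- lapply(params, function(p) array(0, dim(p)))
  env$v <- lapply(params, function(p) array(0, dim(p)))
  env$t <- 0L
  env
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  params$emb[1, ] <- 0
  params
}

#' Train an ensemble of predictors
#'
#' Trains `n_members` independent runs that differ only in their seed
#' (consecutive seeds from `spec$seed`) and averages their predictions;
#' averaging over independently initialised runs removes the run-to-run
#' randomness of a single model. The conventional ensemble size is 20.
#'
#' @param data,pseudo_map,config,spec As in [fit_affinity_model()].
#' @param n_members Number of members (default 20).
#' @param verbose Print progress.
#' @return An object of class `rpe_ensemble` with elements `members` and
#'   `member_seeds`.
#' @export
train_ensemble <- function(data, pseudo_map, config = model_config(),
                           spec = train_spec(), n_members = 20L,
                           verbose = FALSE) {
  stopifnot(n_members >= 1)
  seeds <- spec$seed + seq_len(n_members) - 1L
  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    sp <- spec
    sp$seed <- seeds[k]
    members[[k]] <- tryCatch(
      fit_affinity_model(data, pseudo_map, config, sp, verbose = FALSE),
      error = function(e) {
        stop(sprintf("Ensemble member %d failed: %s", k, conditionMessage(e)),
             call. = FALSE)
      })
    if (verbose) message("trained ensemble member ", k, "/", n_members)
  }
  structure(list(members = members, member_seeds = seeds),
            class = "rpe_ensemble")
}

#' @export
print.rpe_ensemble <- function(x, ...) {
  cat("<rpe_ensemble> ", length(x$members), " member(s), seeds ",
      paste(x$member_seeds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict with an ensemble (arithmetic mean of member predictions)
#'
#' @param object An `rpe_ensemble`.
#' @param newdata Tibble with `allele`, `peptide`.
#' @param ... Passed to the member predict method.
#' @return `newdata` with a `.pred` column (mean over members).
#' @export
predict.rpe_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members,
                  function(m) predict(m, newdata, ...)$.pred,
                  numeric(nrow(newdata)))
  newdata$.pred <- if (nrow(newdata) == 1L) mean(preds) else rowMeans(preds)
  tibble::as_tibble(newdata)
}
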