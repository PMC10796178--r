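#' Model configuration
#'
#' Describes the network topology: an embedding of the 441 residue-pair
#' codes (+ a frozen zero vector for padding), a (34, 1) fusion convolution
#' contracting the MHC axis onto the 20 peptide positions, a multi-scale
#' convolution stage (parallel kernels 1/3/5 with 32/64/128 filters, then
#' 1/3/5/7 with 128/256/512/1024), stride-1 max-pool smoothing of widths 2
#' and 3, a kernel-1 convolution, two parallel LSTM blocks (one- and
#' two-layer) whose hidden sequences are concatenated, a final valid
#' convolution of kernel 9 (the binding-core width) leaving 12 positions,
#' and a fully connected + sigmoid head.
#'
#' `scale_factor` multiplies every channel count (rounded up) so the same
#' topology can be exercised at desk scale; kernel sizes and the sequence
#' axis are untouched.
#'
#' @param embedding_dim Embedding dimension of pair codes (default 16).
#' @param conv1_filters,conv2_filters Filter counts for the parallel
#'   convolution branches (kernels 1/3/5 and 1/3/5/7).
#' @param conv3_filters Filters of the kernel-1 convolution (default 256).
#' @param lstm_hidden LSTM hidden size (default 128).
#' @param final_filters Filters of the final kernel-9 convolution (default 128).
#' @param fc_dim Width of the fully connected layer (default 64).
#' @param dropout Dropout rate applied after each pooling stage (default 0.1).
#' @param scale_factor Multiplier in (0, 1] on all channel counts.
#' @param fuse_bias Whether the fusion convolution carries a bias.
#' @return An object of class `rpe_config`.
#' @examples
#' cfg <- model_config(scale_factor = 0.25)
#' cfg$conv2_c
#' @export
model_config <- function(embedding_dim = 16L,
                         conv1_filters = c(32L, 64L, 128L),
                         conv2_filters = c(128L, 256L, 512L, 1024L),
                         conv3_filters = 256L,
                         lstm_hidden = 128L,
                         final_filters = 128L,
                         fc_dim = 64L,
                         dropout = 0.1,
                         scale_factor = 1,
                         fuse_bias = TRUE) {
  stopifnot(embedding_dim >= 1, length(conv1_filters) == 3,
            length(conv2_filters) == 4,
            dropout >= 0, dropout < 1,
            scale_factor > 0, scale_factor <= 1)
  sc <- function(x) as.integer(ceiling(x * scale_factor))
  cfg <- list(
    embedding_dim = as.integer(embedding_dim),
    conv1_k = c(1L, 3L, 5L), conv1_c = sc(conv1_filters),
    pool1 = 2L,
    conv2_k = c(1L, 3L, 5L, 7L), conv2_c = sc(conv2_filters),
    pool2 = 3L,
    conv3_c = sc(conv3_filters),
    lstm_hidden = sc(lstm_hidden),
    final_k = 9L, final_c = sc(final_filters),
    fc_dim = sc(fc_dim),
    dropout = dropout,
    fuse_bias = isTRUE(fuse_bias),
    scale_factor = scale_factor,
    peptide_len = 20L, mhc_len = 34L, vocab_size = 442L
  )
  if (cfg$final_k != 9L) stop("final convolution kernel must be 9", call. = FALSE)
  if (cfg$peptide_len - cfg$final_k + 1L < 1L) {
    stop("configuration leaves the final convolution no positions", call. = FALSE)
  }
  structure(cfg, class = "rpe_config")
}

#' @export
print.rpe_config <- function(x, ...) {
  cat("<rpe_config> embedding", x$embedding_dim,
      "| conv1", paste(x$conv1_c, collapse = "+"),
      "| conv2", paste(x$conv2_c, collapse = "+"),
      "| conv3", x$conv3_c, "| lstm", x$lstm_hidden,
      "| final", x$final_c, "x k9 | fc", x$fc_dim,
      "| scale", x$scale_factor, "\n")
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Parameter shapes implied by a configuration
#' @param config An `rpe_config`.
#' @return Named list of `c(rows, cols)` integer pairs.
#' @keywords internal
param_shapes <- function(config) {
  E <- config$embedding_dim
  C1 <- sum(config$conv1_c)
  C2 <- sum(config$conv2_c)
  H <- config$lstm_hidden
  shapes <- list(
    emb = c(config$vocab_size, E),
    fuse_W = c(config$mhc_len * E, E),
    fuse_b = c(E, 1L)
  )
  for (b in seq_along(config$conv1_k)) {
    shapes[[paste0("c1_W_", b)]] <- c(config$conv1_c[b], E * config$conv1_k[b])
    shapes[[paste0("c1_b_", b)]] <- c(config$conv1_c[b], 1L)
  }
  for (b in seq_along(config$conv2_k)) {
    shapes[[paste0("c2_W_", b)]] <- c(config$conv2_c[b], C1 * config$conv2_k[b])
    shapes[[paste0("c2_b_", b)]] <- c(config$conv2_c[b], 1L)
  }
  shapes$c3_W <- c(config$conv3_c, C2)
  shapes$c3_b <- c(config$conv3_c, 1L)
  for (blk in c("lA1", "lB1")) {
    shapes[[paste0(blk, "_Wx")]] <- c(4L * H, config$conv3_c)
    shapes[[paste0(blk, "_Wh")]] <- c(4L * H, H)
    shapes[[paste0(blk, "_b")]] <- c(4L * H, 1L)
  }
  shapes$lB2_Wx <- c(4L * H, H)
  shapes$lB2_Wh <- c(4L * H, H)
  shapes$lB2_b <- c(4L * H, 1L)
  shapes$fin_W <- c(config$final_c, 2L * H * config$final_k)
  shapes$fin_b <- c(config$final_c, 1L)
  n_out_pos <- config$peptide_len - config$final_k + 1L
  shapes$fc_W <- c(config$fc_dim, config$final_c * n_out_pos)
  shapes$fc_b <- c(config$fc_dim, 1L)
  shapes$out_w <- c(1L, config$fc_dim)
  shapes$out_b <- c(1L, 1L)
  shapes
}

#' Total trainable parameter count of a configuration
#'
#' A deterministic function of the configuration. The pad embedding row is
#' frozen at zero and is not counted; the fusion bias is counted only when
#' enabled.
#'
#' @param config An `rpe_config`.
#' @return Integer count.
#' @export
n_params <- function(config) {
  shapes <- param_shapes(config)
  total <- sum(vapply(shapes, prod, numeric(1)))
  total <- total - config$embedding_dim            # frozen pad row
  if (!config$fuse_bias) total <- total - config$embedding_dim
  as.integer(total)
}

#' Initialize network parameters
#'
#' He initialisation for convolution/FC weights, uniform
#' `(-1/sqrt(H), 1/sqrt(H))` for LSTM weights with the forget-gate bias set
#' to 1, `N(0, 0.1)` embeddings with the pad row frozen at zero.
#'
#' @param config An `rpe_config`.
#' @param seed Integer seed; initialisation is fully reproducible.
#' @return Named list of parameter matrices.
#' @keywords internal
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  shapes <- param_shapes(config)
  H <- config$lstm_hidden
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (nm == "emb") {
      m <- matrix(stats::rnorm(prod(sh), sd = 0.1), sh[1], sh[2])
      m[1, ] <- 0
      m
    } else if (grepl("_b$|out_b", nm)) {
      m <- matrix(0, sh[1], sh[2])
      if (grepl("^l[AB]", nm)) m[(H + 1):(2 * H), 1] <- 1  # forget gate
      m
    } else if (grepl("^l[AB]", nm)) {
      matrix(stats::runif(prod(sh), -1 / sqrt(H), 1 / sqrt(H)), sh[1], sh[2])
    } else {
      fan_in <- sh[2]
      matrix(stats::rnorm(prod(sh), sd = sqrt(2 / fan_in)), sh[1], sh[2])
    }
  })
  names(params) <- names(shapes)
  params
}

# configuration in the exact form the C++ kernel expects
as_cpp_config <- function(config) {
  config[c("embedding_dim", "conv1_k", "conv1_c", "pool1", "conv2_k", "conv2_c",
           "pool2", "conv3_c", "lstm_hidden", "final_k", "final_c", "fc_dim",
           "dropout", "fuse_bias")]
}
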