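#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted predictor's loss curves
#'
#' @param object An `affinity_predictor` with a training log.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE by epoch.
#' @export
autoplot.affinity_predictor <- function(object, ...) {
  log <- tidy(object)
  if (nrow(log) == 0L) stop("Predictor has no training log.", call. = FALSE)
  long <- tidyr::pivot_longer(log, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a motif's per-position residue frequencies and information content
#'
#' A text-based logo: residues stacked per core position, letter size
#' proportional to frequency, with the per-position information content as
#' the panel strip.
#'
#' @param object A `motif_matrix`.
#' @param min_frequency Residues below this frequency are not drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_matrix <- function(object, min_frequency = 0.05, ...) {
  df <- tidy(object)
  df <- df[df$frequency >= min_frequency, , drop = FALSE]
  df <- dplyr::arrange(df, .data$position, .data$frequency)
  df <- dplyr::mutate(dplyr::group_by(df, .data$position),
                      ytop = cumsum(.data$frequency),
                      ymid = .data$ytop - .data$frequency / 2)
  ic <- information_content(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid,
                                   label = .data$residue,
                                   size = .data$frequency)) +
    ggplot2::geom_text(ggplot2::aes(colour = .data$residue), fontface = "bold",
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none") +
    ggplot2::scale_x_continuous(breaks = 1:9,
                                labels = sprintf("%d\n(%.1f)", 1:9, ic)) +
    ggplot2::labs(title = paste("Binding motif:", object$allele),
                  x = "core position (information content, bits)",
                  y = "cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Plot the window scores of a core prediction
#'
#' @param object A `core_prediction`.
#' @param ... Unused.
#' @return A ggplot of predicted affinity by window offset; the selected
#'   core window is highlighted.
#' @export
autoplot.core_prediction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$score,
                                   fill = .data$is_core)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(title = paste0(object$allele, ": ", object$peptide),
                  subtitle = paste("core", object$core, "at offset", object$offset),
                  x = "window offset", y = "predicted affinity") +
    ggplot2::theme_minimal()
}

#' Scatter plot of predicted vs measured affinity
#'
#' @param table Prediction tibble with `y` (or `y_true`) and `.pred`.
#' @return A ggplot with the binder threshold marked on both axes.
#' @export
plot_predictions <- function(table) {
  y <- if ("y_true" %in% names(table)) table$y_true else table$y
  df <- tibble::tibble(y = y, .pred = table$.pred)
  thr <- affinity_threshold()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$.pred)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dotted", colour = "firebrick") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "measured affinity", y = "predicted affinity") +
    ggplot2::theme_minimal()
}
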