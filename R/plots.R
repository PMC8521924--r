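# ggplot2 views of the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Butterfly / stacked-trace plot of epochs
#'
#' @param object an [epoch_set()].
#' @param epochs which epochs to draw (default: up to first 4).
#' @param spacing vertical offset between channels, in microvolts.
#' @param ... unused.
#' @method autoplot epoch_set
#' @export
autoplot.epoch_set <- function(object, epochs = NULL, spacing = NULL, ...) {
  epochs <- epochs %||% seq_len(min(4L, n_epochs(object)))
  spacing <- spacing %||% (4 * stats::sd(object$data))
  df <- as_tibble.epoch_set(subset_epochs(object, epochs))
  df$epoch_index <- factor(epochs[df$epoch_index],
                           labels = paste("epoch", epochs))
  df$offset <- spacing * (match(df$channel, object$channel_names) - 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value + .data$offset,
                                   group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~epoch_index) +
    ggplot2::labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V, offset)"))) +
    ggplot2::theme_minimal()
}

#' Anomaly-score distribution with the contamination threshold
#'
#' @param object an `artifact_detection` tibble from [run_detection()].
#' @param ... unused.
#' @method autoplot artifact_detection
#' @export
autoplot.artifact_detection <- function(object, ...) {
  thr <- min(object$score[object$flag])
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$score, fill = .data$flag)) +
    ggplot2::geom_histogram(bins = 50, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "anomaly score (higher = more anomalous)", y = "epochs",
                  fill = "flagged") +
    ggplot2::theme_minimal()
}

#' Per-offset training loss of a gap-interpolation ensemble
#' @param object an `interpolator_ensemble`.
#' @param ... unused.
#' @method autoplot interpolator_ensemble
#' @export
autoplot.interpolator_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy.interpolator_ensemble(object),
                  ggplot2::aes(x = .data$offset, y = .data$final_loss)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "gap offset (samples)", y = "final training MSE (scaled)") +
    ggplot2::theme_minimal()
}

#' Downstream-probe accuracies by variant
#' @param object a `downstream_probe` tibble.
#' @param ... unused.
#' @method autoplot downstream_probe
#' @export
autoplot.downstream_probe <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$variant, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "fold accuracy") +
    ggplot2::theme_minimal()
}

#' Overlay a corrected epoch on its raw version
#'
#' @param raw,corrected `epoch_set`s before and after [correct_epochs()].
#' @param epoch epoch index to draw.
#' @param channels channels to draw (default first 4).
#' @export
plot_correction <- function(raw, corrected, epoch, channels = NULL) {
  channels <- channels %||% seq_len(min(4L, n_channels(raw)))
  t <- (seq_len(n_samples(raw)) - 1) / raw$fs
  df <- dplyr::bind_rows(
    tibble::tibble(variant = "raw",
                   tidyr::expand_grid(channel = channels, time = t)),
    tibble::tibble(variant = "corrected",
                   tidyr::expand_grid(channel = channels, time = t)))
  df$value <- c(t(epoch_data(raw, epoch)[channels, , drop = FALSE]),
                t(epoch_data(corrected, epoch)[channels, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$variant)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V)"))) +
    ggplot2::theme_minimal()
}
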