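# ggplot2 displays for the package's result types.

#' Plot simulated or preprocessed PPG traces
#'
#' @param data Records tibble (plots `corrupted`, falling back to `clean`)
#'   or windows tibble (plots `samples`).
#' @param n Number of traces to show (default 6).
#' @param column Which list-column to draw; default picks `corrupted`,
#'   `samples` or `clean`, whichever exists first.
#' @return A ggplot object, one facet per trace.
#' @export
plot_ppg <- function(data, n = 6, column = NULL) {
  column <- column %||%
    intersect(c("corrupted", "samples", "clean"), names(data))[1]
  if (is.na(column)) abort_field("column", "no trace list-column found")
  idx <- seq_len(min(n, nrow(data)))
  fs <- if ("fs" %in% names(data)) data$fs[idx] else
    if ("fs_eff" %in% names(data)) data$fs_eff[idx] else 1
  fs <- rep_len(fs, length(idx))
  lab <- if (all(c("rhythm", "noise_factor") %in% names(data))) {
    sprintf("%s, noise %g", data$rhythm[idx], data$noise_factor[idx])
  } else paste("trace", idx)
  df <- purrr::map_dfr(seq_along(idx), function(j) {
    y <- data[[column]][[idx[j]]]
    tibble::tibble(trace = factor(lab[j], levels = unique(lab)),
                   time = (seq_along(y) - 1) / fs[j],
                   value = y)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = column) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.cdae <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h[c("epoch", "train_mse", "val_mse")],
                            -"epoch", names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Denoising autoencoder training",
                  y = "mean squared error") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for fitted objects
#'
#' Training-history curves for the autoencoder and classifier.
#'
#' @param object A fitted `cdae` or `afnet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
#' @export
autoplot.afnet <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = paste("Training history,", object$variant)) +
    ggplot2::theme_minimal()
}

#' Overlay a class activation map on its window
#'
#' @param samples Numeric window (length L).
#' @param cam Numeric saliency values (length L, in `[0, 1]`), e.g. one row
#'   of [class_activation_map()] output.
#' @param fs Effective sampling rate (Hz) for the time axis.
#' @return A ggplot object: the trace coloured by saliency.
#' @export
plot_cam <- function(samples, cam, fs = 32) {
  df <- tibble::tibble(time = (seq_along(samples) - 1) / fs,
                       value = samples, saliency = cam)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$saliency)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "standardised PPG",
                  colour = "saliency") +
    ggplot2::theme_minimal()
}

#' Scatter a 2-D embedding projection
#'
#' @param projection Tibble from [embedding_projection()].
#' @param labels Optional factor (e.g. true rhythm) colouring the points.
#' @return A ggplot object.
#' @export
plot_projection <- function(projection, labels = NULL) {
  df <- projection
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2")
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
}
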