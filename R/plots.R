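# ggplot2 views of the main result types.

#' Plot a stimulation pulse train
#'
#' Raster of pulse times grouped by duty cycle.
#'
#' @param train A `pulse_train`.
#' @param ... Passed to [segment_train()].
#' @return A ggplot object.
#' @export
plot_pulse_train <- function(train, ...) {
  seg <- segment_train(train, ...)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$t_s, y = .data$cycle)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time (s)", y = "duty cycle") +
    ggplot2::theme_minimal()
}

#' Plot a dF/F0 trace with detected spikes
#'
#' @param dff A `dff_trace`.
#' @param spikes Optional `spike_result` for the same trace.
#' @return A ggplot object.
#' @export
plot_dff <- function(dff, spikes = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  d <- tibble::tibble(time_s = (seq_along(dff$dff) - 1) / dff$frame_rate,
                      dff = dff$dff)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
  if (!is.null(spikes)) {
    p <- p +
      ggplot2::geom_hline(yintercept = spikes$threshold, linetype = 2,
                          colour = "grey50") +
      ggplot2::geom_point(
        data = d[spikes$spike_frames, , drop = FALSE],
        colour = "red", size = 1)
  }
  p
}

#' Heatmap of a unit matrix
#'
#' @param um A `unit_matrix` (or a plain `k x k` matrix, e.g. a variance
#'   map).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_unit_matrix <- function(um, title = NULL) {
  d <- if (inherits(um, "unit_matrix")) tidy(um) else {
    k <- nrow(um)
    tibble::tibble(row = rep(seq_len(k), times = k),
                   col = rep(seq_len(k), each = k),
                   mean = as.vector(um))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r", title = title) +
    ggplot2::theme_minimal()
}

#' Plot size-binned spine-size changes
#'
#' @param binned Tibble from [delta_size_binned()].
#' @return A ggplot object.
#' @export
plot_delta_size_bins <- function(binned) {
  ggplot2::ggplot(binned,
                  ggplot2::aes(factor(signif(.data$bin_upper, 3)),
                               .data$mean_delta)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_delta - .data$sem_delta,
                   ymax = .data$mean_delta + .data$sem_delta), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "day-4 size bin (upper edge, a.u.)",
                  y = expression(Delta * " size / day-4 size")) +
    ggplot2::theme_minimal()
}

#' Plot an averaged mEPSC event-quantity distribution
#'
#' @param dist Tibble from [averaged_event_distribution()].
#' @param quantity Axis label stub.
#' @return A ggplot object.
#' @export
plot_event_distribution <- function(dist, quantity = "amplitude (pA)") {
  ggplot2::ggplot(dist, ggplot2::aes(.data$bin_left, .data$mean_prop)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = quantity, y = "mean proportion") +
    ggplot2::theme_minimal()
}
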