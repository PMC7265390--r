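#' Plot displacement traces
#'
#' Displacement against time, one facet per needle, with detected beat
#' peaks overlaid when a beats table is supplied.
#'
#' @param traces A trace tibble.
#' @param beats Optional beats tibble from [detect_beats()].
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, beats = NULL) {
  check_columns(traces, trace_cols, "traces")
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$displacement_px)) +
    ggplot2::geom_line(colour = "grey25", linewidth = 0.3) +
    ggplot2::facet_wrap(~needle_id, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "tip displacement (px)") +
    ggplot2::theme_minimal()
  if (!is.null(beats) && nrow(beats) > 0) {
    peaks <- beats %>%
      left_join(traces, by = "needle_id", relationship = "many-to-many") %>%
      group_by(.data$needle_id, .data$peak_s) %>%
      filter(abs(.data$time_s - .data$peak_s) ==
               min(abs(.data$time_s - .data$peak_s))) %>%
      slice(1) %>% ungroup()
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(x = .data$peak_s,
                                              y = .data$displacement_px),
                                 colour = "firebrick", size = 1.2)
  }
  p
}

#' Render one frame of a recording with tracked positions
#'
#' @param stack A [frame_stack()].
#' @param frame 0-based frame index.
#' @param tracks Optional tracks tibble to overlay.
#' @return A ggplot object.
#' @export
plot_frame <- function(stack, frame = 0, tracks = NULL) {
  stopifnot(inherits(stack, "nb_frame_stack"))
  m <- stack$frames[[frame + 1L]]
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$intensity <- as.vector(t(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(tracks)) {
    tk <- tracks[tracks$frame == frame & tracks$missing == 0L, ]
    p <- p + ggplot2::geom_point(
      data = tk, ggplot2::aes(.data$x_px, .data$y_px),
      colour = "red", shape = 3, inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contraction summary
#'
#' Beats per 10 s by needle and window.
#'
#' @param object An `nb_summary` from [summarize_contractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_summary
#' @export
autoplot.nb_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_needle,
                  ggplot2::aes(x = factor(.data$needle_id),
                               y = .data$beats_per_10s,
                               fill = factor(.data$window))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "needle", y = "beats per 10 s", fill = "window") +
    ggplot2::theme_minimal()
}

#' Plot a normalized drug-response time course
#'
#' Normalized tip-movement amplitude against time with the baseline level
#' marked at 1.
#'
#' @param object An `nb_timecourse` from [normalize_to_baseline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_timecourse
#' @export
autoplot.nb_timecourse <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s / 60,
                               y = .data$normalized_amplitude)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::labs(x = "time (min)", y = "normalized amplitude",
                  colour = "event") +
    ggplot2::theme_minimal()
}
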