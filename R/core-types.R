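#' Frame stack: an ordered grayscale recording with a frame rate
#'
#' The raw observation type: a list of equally sized 2-D intensity matrices
#' (8-bit scale, values in 0--255) together with the acquisition frame rate.
#' Matrix element `[i, j]` is the pixel centred at `(x = j, y = i)`; the
#' origin is the top-left corner, x runs rightward, y downward. Frame indices
#' are 0-based and time is `frame / fps` seconds.
#'
#' @param frames List of numeric matrices, all with identical dimensions.
#' @param fps Frames per second (Hz), must be positive.
#' @param pixel_size_um Optional physical pixel size in micrometres per pixel.
#' @return An object of class `nb_frame_stack`.
#' @examples
#' fs <- frame_stack(list(matrix(0, 24, 32), matrix(1, 24, 32)), fps = 30)
#' n_frames(fs)
#' @export
frame_stack <- function(frames, fps, pixel_size_um = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    abort("`frames` must be a non-empty list of matrices.",
          class = "needlebeat_empty_stack")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    abort("every frame must be a matrix.")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must share the same height and width.",
          class = "needlebeat_inconsistent_size")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  structure(
    list(frames = frames, fps = fps, pixel_size_um = pixel_size_um),
    class = "nb_frame_stack"
  )
}

#' @rdname frame_stack
#' @param x A `nb_frame_stack`.
#' @export
n_frames <- function(x) length(x$frames)

#' @export
dim.nb_frame_stack <- function(x) c(dim(x$frames[[1]]), length(x$frames))

#' @export
print.nb_frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<nb_frame_stack> %d frames of %d x %d px at %g fps (%.2f s)\n",
    length(x$frames), d[2], d[1], x$fps, length(x$frames) / x$fps
  ))
  invisible(x)
}

#' Field-stimulation protocol
#'
#' Describes a train of bipolar field pulses used to pace the construct.
#' The waveform period is split exactly between the pulse and the
#' inter-pulse gap: `pulse_width + inter_pulse_gap == 1000 / frequency` ms.
#'
#' @param frequency Pacing frequency in Hz, positive.
#' @param pulse_width Pulse duration in ms; must be shorter than the period.
#' @param voltage Pulse amplitude in V (metadata; default 20 V).
#' @return An object of class `nb_stim_protocol` with fields `voltage`,
#'   `pulse_width`, `frequency` and `inter_pulse_gap` (ms).
#' @examples
#' pulse_schedule(1, 10)  # 990 ms gap
#' pulse_schedule(2, 10)  # 490 ms gap
#' @export
pulse_schedule <- function(frequency, pulse_width = 10, voltage = 20) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    abort("`frequency` must be a single positive number (Hz).",
          class = "needlebeat_invalid_protocol")
  }
  period_ms <- 1000 / frequency
  if (!is.numeric(pulse_width) || pulse_width < 0 || pulse_width >= period_ms) {
    abort(sprintf(
      "`pulse_width` (%s ms) must lie in [0, period = %g ms).",
      format(pulse_width), period_ms
    ), class = "needlebeat_invalid_protocol")
  }
  structure(
    list(
      voltage = voltage,
      pulse_width = pulse_width,
      frequency = frequency,
      inter_pulse_gap = period_ms - pulse_width
    ),
    class = "nb_stim_protocol"
  )
}

#' @export
print.nb_stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<nb_stim_protocol> %g V, %g Hz, %g ms pulses every %g ms (gap %g ms)\n",
    x$voltage, x$frequency, x$pulse_width,
    x$pulse_width + x$inter_pulse_gap, x$inter_pulse_gap
  ))
  invisible(x)
}

# internal validators for the tabular types -------------------------------

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", what))
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}

track_cols <- c("needle_id", "frame", "time_s", "x_px", "y_px",
                "confidence", "missing")
trace_cols <- c("needle_id", "frame", "time_s", "displacement_px")
beat_cols  <- c("needle_id", "onset_s", "peak_s", "relax_s", "amplitude_px")
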