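#' Tidy a contraction summary
#'
#' One row per needle and window with the beat count, beats per 10 s,
#' mean per-beat amplitude and amplitude CV.
#'
#' @param x An `nb_summary` from [summarize_contractions()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nb_summary
#' @export
tidy.nb_summary <- function(x, ...) {
  x$per_needle
}

#' Glance at a contraction summary
#'
#' A one-row overview: number of needles and windows, grand mean rate and
#' amplitude, and the cross-needle synchronisation index.
#'
#' @param x An `nb_summary`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance nb_summary
#' @export
glance.nb_summary <- function(x, ...) {
  tibble(
    n_needles = length(unique(x$per_needle$needle_id)),
    n_windows = max(x$per_needle$window),
    window_s = x$window_s,
    mean_beats_per_10s = mean(x$per_needle$beats_per_10s),
    mean_amplitude_px = mean(x$per_needle$mean_amplitude_px, na.rm = TRUE),
    sync_index = x$sync_index
  )
}

#' Tidy a normalized time course
#'
#' @param x An `nb_timecourse` from [normalize_to_baseline()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy nb_timecourse
#' @export
tidy.nb_timecourse <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Glance at a normalized time course
#'
#' @param x An `nb_timecourse`.
#' @param ... Unused.
#' @return A one-row tibble with the amplitude extremes relative to
#'   baseline and the final level.
#' @method glance nb_timecourse
#' @export
glance.nb_timecourse <- function(x, ...) {
  tibble(
    n_timepoints = nrow(x),
    min_normalized = min(x$normalized_amplitude),
    max_normalized = max(x$normalized_amplitude),
    final_normalized = x$normalized_amplitude[nrow(x)]
  )
}
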