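#' Beat detection configuration
#'
#' @param smoothing_window Moving-average window, s (default 0.1 s).
#' @param min_prominence Peak prominence threshold in px, or `"auto"`:
#'   `auto_fraction` of the trace's robust (5th--95th percentile) range.
#' @param auto_fraction Fraction of the robust range used by the auto
#'   threshold (default 0.2).
#' @param min_interbeat Minimum separation between detected peaks, s
#'   (default 0.2 s, admitting pacing up to ~4 Hz).
#' @param amplitude `"local-trough"` (default): per-beat amplitude is the
#'   peak value minus the higher of the two flanking troughs, so incomplete
#'   relaxation under fast pacing reduces amplitude; or `"above-rest"`: the
#'   peak displacement itself.
#' @param max_gap_frames Missing-sample gaps up to this many frames are
#'   linearly interpolated before smoothing; longer gaps split the trace
#'   into independently analysed segments.
#' @param noise_floor Traces whose robust range falls below this (px) are
#'   treated as beat-free.
#' @return An object of class `nb_beat_config`.
#' @export
beat_config <- function(smoothing_window = 0.1, min_prominence = "auto",
                        auto_fraction = 0.2, min_interbeat = 0.2,
                        amplitude = c("local-trough", "above-rest"),
                        max_gap_frames = 2, noise_floor = 0.05) {
  amplitude <- match.arg(amplitude)
  stopifnot(min_interbeat > 0, smoothing_window >= 0)
  structure(
    list(smoothing_window = smoothing_window,
         min_prominence = min_prominence, auto_fraction = auto_fraction,
         min_interbeat = min_interbeat, amplitude = amplitude,
         max_gap_frames = as.integer(max_gap_frames),
         noise_floor = noise_floor),
    class = "nb_beat_config"
  )
}

# centred moving average with reflected edges
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[length(x) - seq_len(half)]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[half + seq_along(x)]
}

# indices of local maxima (strict rise, non-strict fall)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of each peak index within x. Displacement traces
# have a known resting level (0 by construction), so a side truncated by
# the recording edge falls back to `edge_base` rather than the partial
# descent -- otherwise a beat peaking just before the recording ends would
# be discarded because its relaxation was clipped.
peak_prominence <- function(x, peaks, edge_base = min(x)) {
  vapply(seq_along(peaks), function(k) {
    p <- peaks[k]; v <- x[p]
    lefts <- peaks[peaks < p & x[peaks] >= v]
    left_base <- if (length(lefts)) min(x[max(lefts):p])
                 else min(x[1:p], edge_base)
    rights <- peaks[peaks > p & x[peaks] >= v]
    right_base <- if (length(rights)) min(x[p:min(rights)])
                  else min(x[p:length(x)], edge_base)
    v - max(left_base, right_base)
  }, numeric(1))
}

# greedy refractory filter: keep higher peaks first, enforce min separation
enforce_separation <- function(peaks, heights, min_sep_frames) {
  keep <- integer(0)
  for (p in peaks[order(-heights)]) {
    if (all(abs(keep - p) >= min_sep_frames)) keep <- c(keep, p)
  }
  sort(keep)
}

# split a displacement vector into segments at long NA gaps; interpolate
# short gaps. returns list of (start_index, values)
split_segments <- function(d, max_gap) {
  n <- length(d)
  if (!anyNA(d)) return(list(list(start = 1L, values = d)))
  filled <- zoo::na.approx(d, na.rm = FALSE, maxgap = max_gap)
  isna <- is.na(filled)
  segs <- list()
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) {
      segs[[length(segs) + 1]] <-
        list(start = starts[i], values = filled[starts[i]:ends[i]])
    }
  }
  segs
}

detect_beats_vector <- function(d, fps, t0, config) {
  empty <- tibble(onset_s = double(), peak_s = double(),
                  relax_s = double(), amplitude_px = double())
  w <- max(1L, round(config$smoothing_window * fps))
  s <- smooth_ma(d, w)
  q <- quantile(s, c(0.05, 0.95), na.rm = TRUE)
  rng <- q[2] - q[1]
  if (rng < config$noise_floor) return(empty)
  prom_thr <- if (identical(config$min_prominence, "auto")) {
    config$auto_fraction * rng
  } else config$min_prominence
  peaks <- local_maxima(s)
  if (length(peaks) == 0) return(empty)
  prom <- peak_prominence(s, peaks, edge_base = q[1])
  peaks <- peaks[prom >= prom_thr]
  if (length(peaks) == 0) return(empty)
  peaks <- enforce_separation(peaks, s[peaks],
                              ceiling(config$min_interbeat * fps))
  n <- length(s)
  bounds <- c(1L, peaks, n)
  out <- lapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    left_lo <- bounds[k]           # previous peak (or trace start)
    right_hi <- bounds[k + 2L]     # next peak (or trace end)
    li <- left_lo + which.min(s[left_lo:p]) - 1L
    ri <- p + which.min(s[p:right_hi]) - 1L
    left_trough <- s[li]; right_trough <- s[ri]
    amp <- if (config$amplitude == "local-trough") {
      s[p] - max(left_trough, right_trough)
    } else s[p]
    # 10% crossings for onset and relaxation
    on_level <- left_trough + 0.1 * (s[p] - left_trough)
    seg <- s[li:p]
    oi <- li + max(which(seg <= on_level)) - 1L
    off_level <- right_trough + 0.1 * (s[p] - right_trough)
    seg2 <- s[p:ri]
    fi <- p + min(which(seg2 <= off_level)) - 1L
    tibble(onset_s = t0 + (oi - 1) / fps, peak_s = t0 + (p - 1) / fps,
           relax_s = t0 + (fi - 1) / fps, amplitude_px = amp)
  })
  out <- bind_rows(out)
  out[out$amplitude_px > 0, ]
}

#' Detect contraction events in displacement traces
#'
#' Smooths each trace with a short moving average, picks local maxima whose
#' topographic prominence exceeds a threshold (by default 20% of the robust
#' 5th--95th percentile displacement range), and enforces a refractory
#' separation between peaks. Per-beat amplitude ("top movement") is measured
#' against the higher flanking trough; onset and relaxation times come from
#' 10% crossings. A flat trace yields an empty beat table, not an error.
#'
#' @param traces A trace tibble (`needle_id`, `frame`, `time_s`,
#'   `displacement_px`), possibly covering several needles.
#' @param fps Frames per second; taken from `attr(traces, "fps")` or the
#'   time column when omitted.
#' @param config A [beat_config()].
#' @return A beats tibble: `needle_id`, `onset_s`, `peak_s`, `relax_s`,
#'   `amplitude_px`.
#' @export
detect_beats <- function(traces, fps = NULL, config = beat_config()) {
  check_columns(traces, trace_cols, "traces")
  if (is.null(fps)) fps <- attr(traces, "fps")
  if (is.null(fps)) {
    dt <- diff(sort(unique(traces$time_s)))
    if (length(dt) == 0) abort("cannot infer fps from a single frame.")
    fps <- 1 / median(dt)
  }
  out <- list()
  for (id in sort(unique(traces$needle_id))) {
    tr <- traces[traces$needle_id == id, ]
    tr <- tr[order(tr$frame), ]
    segs <- split_segments(tr$displacement_px, config$max_gap_frames)
    for (sg in segs) {
      if (length(sg$values) < 2 * fps * config$min_interbeat) next
      b <- detect_beats_vector(sg$values, fps,
                               tr$time_s[sg$start], config)
      if (nrow(b) > 0) out[[length(out) + 1]] <- mutate(b, needle_id = id,
                                                        .before = 1)
    }
  }
  if (length(out) == 0) {
    return(tibble(needle_id = integer(), onset_s = double(),
                  peak_s = double(), relax_s = double(),
                  amplitude_px = double()))
  }
  arrange(bind_rows(out), .data$needle_id, .data$peak_s)
}

#' Beating rate in beats per 10 s
#'
#' Counts beat peaks inside a time window and rescales the count to the
#' conventional 10-second reporting window.
#'
#' @param beats A beats tibble (see [detect_beats()]); may be empty.
#' @param window `c(t0, t1)` in seconds, `t1 > t0`.
#' @return A tibble with `needle_id`, `n_beats`, `beats_per_10s` (one row
#'   per needle; a single all-zero row for an empty input).
#' @export
beating_rate <- function(beats, window = c(0, 10)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  span <- window[2] - window[1]
  if (nrow(beats) == 0) {
    return(tibble(needle_id = NA_integer_, n_beats = 0L, beats_per_10s = 0))
  }
  beats %>%
    group_by(.data$needle_id) %>%
    summarise(
      n_beats = sum(.data$peak_s >= window[1] & .data$peak_s < window[2]),
      .groups = "drop"
    ) %>%
    mutate(beats_per_10s = .data$n_beats * 10 / span)
}

#' Per-beat amplitude summary
#'
#' Arithmetic mean and coefficient of variation of per-beat amplitudes.
#' An empty beat table signals a `needlebeat_no_beats` condition: the caller
#' decides whether that means amplitude 0 (as at a post-toxicity endpoint
#' where contraction has ceased) or an analysis failure.
#'
#' @param beats A beats tibble.
#' @return A tibble with `needle_id`, `n_beats`, `mean_amplitude_px`,
#'   `amplitude_cv`.
#' @export
amplitude_summary <- function(beats) {
  if (nrow(beats) == 0) {
    abort("no beats to summarise.", class = "needlebeat_no_beats")
  }
  beats %>%
    group_by(.data$needle_id) %>%
    summarise(
      n_beats = dplyr::n(),
      mean_amplitude_px = mean(.data$amplitude_px),
      amplitude_cv = ifelse(dplyr::n() > 1,
                            sd(.data$amplitude_px) / mean(.data$amplitude_px),
                            0),
      .groups = "drop"
    )
}

#' Cross-needle beat synchronisation index
#'
#' For every ordered needle pair (i, j), the fraction of beats on needle i
#' that have a beat on needle j within `tolerance` seconds; the index is
#' the mean over ordered pairs, in [0, 1]. It is 1 exactly when every beat
#' co-occurs across all needles within tolerance. A needle with zero beats
#' contributes 0 to each of its pairs.
#'
#' @param beats A beats tibble covering >= 2 needles.
#' @param tolerance Matching tolerance, s (default 0.15 s).
#' @param needle_ids Optional full set of needle ids, so needles with no
#'   detected beats still contribute zeros.
#' @return A single number in [0, 1].
#' @export
sync_index <- function(beats, tolerance = 0.15, needle_ids = NULL) {
  ids <- if (is.null(needle_ids)) sort(unique(beats$needle_id))
         else sort(unique(needle_ids))
  if (length(ids) < 2) {
    abort("sync_index needs at least two needles.")
  }
  times <- lapply(ids, function(id) beats$peak_s[beats$needle_id == id])
  fracs <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    ti <- times[[i]]; tj <- times[[j]]
    fracs <- c(fracs, if (length(ti) == 0 || length(tj) == 0) 0 else {
      mean(vapply(ti, function(t) any(abs(tj - t) <= tolerance), logical(1)))
    })
  }
  mean(fracs)
}

#' Windowed contraction summary across needles
#'
#' Splits the recording into 10 s windows (the conventional reporting
#' window) and reports, per needle and window, the beat count, beats per
#' 10 s, mean per-beat amplitude and amplitude CV, plus one cross-needle
#' synchronisation index over the whole recording (absent for a single
#' needle).
#'
#' @param traces A trace tibble covering one or more needles with a shared
#'   fps and length.
#' @param config A [beat_config()].
#' @param window_s Summary window length, s (default 10).
#' @param tolerance Synchronisation tolerance, s.
#' @param fps Frames per second (see [detect_beats()]).
#' @return An object of class `nb_summary`: list with `per_needle` (tibble),
#'   `sync_index`, `window_s`, `fps`. Use [tidy()] / [glance()] to extract
#'   tibbles.
#' @export
summarize_contractions <- function(traces, config = beat_config(),
                                   window_s = 10, tolerance = 0.15,
                                   fps = NULL) {
  check_columns(traces, trace_cols, "traces")
  lens <- traces %>% group_by(.data$needle_id) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (length(unique(lens$n)) != 1) {
    abort("traces must share a common length across needles.",
          class = "needlebeat_alignment_error")
  }
  if (is.null(fps)) fps <- attr(traces, "fps")
  if (is.null(fps)) fps <- 1 / median(diff(sort(unique(traces$time_s))))
  total <- max(traces$time_s) + 1 / fps
  n_win <- max(1, floor(total / window_s + 1e-9))
  beats <- detect_beats(traces, fps = fps, config = config)
  ids <- sort(unique(traces$needle_id))
  rows <- list()
  for (wi in seq_len(n_win)) {
    w0 <- (wi - 1) * window_s
    w1 <- min(wi * window_s, total)
    for (id in ids) {
      b <- beats[beats$needle_id == id &
                 beats$peak_s >= w0 & beats$peak_s < w1, ]
      rows[[length(rows) + 1]] <- tibble(
        needle_id = id, window = wi, t_start = w0, t_end = w1,
        n_beats = nrow(b),
        beats_per_10s = nrow(b) * 10 / (w1 - w0),
        mean_amplitude_px = if (nrow(b)) mean(b$amplitude_px) else NA_real_,
        amplitude_cv = if (nrow(b) > 1)
          sd(b$amplitude_px) / mean(b$amplitude_px)
        else if (nrow(b) == 1) 0 else NA_real_
      )
    }
  }
  sync <- if (length(ids) >= 2) {
    sync_index(beats, tolerance = tolerance, needle_ids = ids)
  } else NA_real_
  structure(
    list(per_needle = bind_rows(rows), sync_index = sync,
         window_s = window_s, fps = fps, beats = beats),
    class = "nb_summary"
  )
}

#' @export
print.nb_summary <- function(x, ...) {
  cat(sprintf("<nb_summary> %d needle(s), %d window(s) of %g s",
              length(unique(x$per_needle$needle_id)),
              max(x$per_needle$window), x$window_s))
  if (!is.na(x$sync_index)) cat(sprintf(", sync index %.2f", x$sync_index))
  cat("\n")
  print(x$per_needle)
  invisible(x)
}
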