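#' Cardiac twitch waveform model
#'
#' Parameterises a single needle's contraction kinetics: a
#' difference-of-exponentials twitch kernel (fast contraction, slow
#' relaxation), beat timing that is either spontaneous (a renewal process
#' with Gaussian-jittered inter-beat intervals) or paced by a stimulation
#' protocol with 1:1 capture, and an optional linear baseline drift.
#'
#' Defaults correspond to a visibly beating construct recorded at 30 fps:
#' 8 px peak deflection, 50 ms contraction and 300 ms relaxation time
#' constants, 5% inter-beat interval jitter.
#'
#' @param amplitude Peak tip deflection per twitch, px (>= 0).
#' @param tau_contract Contraction time constant, s (> 0).
#' @param tau_relax Relaxation time constant, s (> 0).
#' @param rate Mean spontaneous beat rate, Hz; ignored when `protocol` given.
#' @param protocol Optional [pulse_schedule()] for paced beating.
#' @param ibi_jitter_cv Coefficient of variation of spontaneous inter-beat
#'   intervals (>= 0).
#' @param drift_px_per_s Linear baseline drift rate, px/s.
#' @return An object of class `nb_twitch_model`.
#' @examples
#' m <- twitch_model(rate = 0.6)
#' twitch_kernel(seq(0, 1, 0.1), m)
#' @export
twitch_model <- function(amplitude = 8, tau_contract = 0.05, tau_relax = 0.3,
                         rate = 1, protocol = NULL, ibi_jitter_cv = 0.05,
                         drift_px_per_s = 0) {
  stopifnot(amplitude >= 0, tau_contract > 0, tau_relax > 0,
            ibi_jitter_cv >= 0)
  if (!is.null(protocol) && !inherits(protocol, "nb_stim_protocol")) {
    abort("`protocol` must be built with pulse_schedule().",
          class = "needlebeat_invalid_protocol")
  }
  structure(
    list(amplitude = amplitude, tau_contract = tau_contract,
         tau_relax = tau_relax, rate = rate, protocol = protocol,
         ibi_jitter_cv = ibi_jitter_cv, drift_px_per_s = drift_px_per_s),
    class = "nb_twitch_model"
  )
}

# time from twitch onset to kernel peak (closed form)
twitch_peak_time <- function(model) {
  tc <- model$tau_contract; tr <- model$tau_relax
  if (isTRUE(all.equal(tc, tr))) tc
  else tc * tr / (tr - tc) * log(tr / tc)
}

#' Evaluate the twitch kernel
#'
#' The displacement kernel is a difference of exponentials,
#' `k(t) = exp(-t / tau_relax) - exp(-t / tau_contract)`, rescaled so its
#' maximum equals `amplitude`; it starts at 0 at `t = 0`. When the two time
#' constants coincide the analytic limit `(t / tau) * exp(1 - t / tau)` is
#' used instead.
#'
#' @param t_since_onset Time(s) since twitch onset, s; values < 0 give 0.
#' @param model A [twitch_model()].
#' @return Displacement in px, same length as `t_since_onset`.
#' @export
twitch_kernel <- function(t_since_onset, model) {
  t <- pmax(t_since_onset, 0)
  a <- model$amplitude
  if (a == 0) return(rep(0, length(t)))
  tc <- model$tau_contract; tr <- model$tau_relax
  if (isTRUE(all.equal(tc, tr))) {
    k <- (t / tc) * exp(1 - t / tc)
  } else {
    tpk <- twitch_peak_time(model)
    norm <- exp(-tpk / tr) - exp(-tpk / tc)
    k <- (exp(-t / tr) - exp(-t / tc)) / norm
  }
  k[t_since_onset < 0] <- 0
  a * k
}

# beat onset times in [0, duration); RNG is only used in spontaneous mode
draw_onsets <- function(model, duration, seed, phase = NULL) {
  if (!is.null(model$protocol)) {
    f <- model$protocol$frequency
    if (f <= 0) abort("paced mode requires frequency > 0.",
                      class = "needlebeat_invalid_protocol")
    ph <- if (is.null(phase)) 0 else phase
    # one beat per delivered pulse: floor(duration * frequency) periods
    n_on <- floor(duration * f + 1e-9)
    onsets <- ph + (seq_len(n_on) - 1) / f
    onsets[onsets < duration - 1e-12]
  } else if (model$rate <= 0) {
    numeric(0)
  } else {
    with_seed(seed, {
      mean_ibi <- 1 / model$rate
      t0 <- if (is.null(phase)) runif(1, 0, mean_ibi) else phase
      onsets <- t0
      repeat {
        ibi <- rnorm(1, mean_ibi, model$ibi_jitter_cv * mean_ibi)
        ibi <- max(ibi, 0.2 * mean_ibi)  # renewal intervals stay positive
        nxt <- onsets[length(onsets)] + ibi
        if (nxt >= duration) break
        onsets <- c(onsets, nxt)
      }
      onsets[onsets < duration]
    })
  }
}

#' Simulate a ground-truth displacement trace
#'
#' Draws beat onsets (paced with 1:1 capture, or a jittered renewal process),
#' superposes the twitch kernel additively over onsets -- so rapid pacing
#' produces incomplete relaxation between beats without any special-casing --
#' and samples the waveform at the frame times. Deterministic given `seed`;
#' the drawn onsets do not depend on `fps`, so re-sampling the same seed at a
#' different frame rate yields the same underlying beat times.
#'
#' @param model A [twitch_model()].
#' @param duration Recording length, s (> 0).
#' @param fps Sampling rate, Hz (> 0).
#' @param seed Integer seed for the spontaneous beat-time jitter.
#' @param needle_id Needle label for the output trace.
#' @param phase Optional onset of the first beat, s. Paced mode defaults to
#'   phase 0 (capture from the first pulse); spontaneous mode defaults to a
#'   uniform draw in `[0, 1/rate)`.
#' @return A list of class `nb_simulation`:
#'   `trace` (tibble: needle_id, frame, time_s, displacement_px),
#'   `beats` (tibble of ground truth: needle_id, onset_s, peak_s,
#'   amplitude_px), plus `fps`, `duration`, `model` and `seed`.
#' @examples
#' sim <- simulate_trace(twitch_model(protocol = pulse_schedule(1, 10)),
#'                       duration = 10, fps = 30, seed = 1)
#' nrow(sim$beats)  # 10 paced beats in 10 s
#' @export
simulate_trace <- function(model, duration, fps, seed = 1L,
                           needle_id = 1L, phase = NULL) {
  stopifnot(duration > 0, fps > 0)
  onsets <- draw_onsets(model, duration, seed, phase)
  nf <- round(duration * fps)
  t <- (seq_len(nf) - 1) / fps
  d <- rep(0, nf)
  for (on in onsets) d <- d + twitch_kernel(t - on, model)
  d <- d + model$drift_px_per_s * t
  tpk <- twitch_peak_time(model)
  structure(
    list(
      trace = tibble(needle_id = as.integer(needle_id),
                     frame = seq_len(nf) - 1L, time_s = t,
                     displacement_px = d),
      beats = tibble(needle_id = as.integer(needle_id), onset_s = onsets,
                     peak_s = onsets + tpk,
                     amplitude_px = rep(model$amplitude, length(onsets))),
      fps = fps, duration = duration, model = model, seed = seed
    ),
    class = "nb_simulation"
  )
}

#' @export
print.nb_simulation <- function(x, ...) {
  cat(sprintf("<nb_simulation> needle %d: %g s at %g fps, %d beats\n",
              x$trace$needle_id[1], x$duration, x$fps, nrow(x$beats)))
  invisible(x)
}

#' Describe a synthetic needle-array scene
#'
#' Geometry and rendering parameters for a needle-array field of view:
#' bright tip blobs on dim shafts over a dark background, each tip deflecting
#' from its rest position along a per-needle unit direction. Defaults render
#' a 320x240 8-bit frame, tip blob sigma 2 px.
#'
#' @param tip_rest_positions Data frame or matrix with columns/cols (x, y):
#'   rest position of each tip, px.
#' @param frame_h,frame_w Frame height and width, px.
#' @param fps Frame rate, Hz.
#' @param duration Recording length, s; `duration * fps >= 2` frames.
#' @param deflection_direction Unit deflection vector(s): length-2 vector
#'   recycled to all needles, or an n x 2 matrix. Default: +x (rightward).
#' @param tip_sigma Gaussian tip blob sigma, px.
#' @param tip_intensity Peak tip intensity above background (8-bit units).
#' @param shaft_intensity,shaft_width,shaft_length Shaft ridge intensity,
#'   Gaussian half-width (px) and length below the tip (px).
#' @param background Background intensity (8-bit units).
#' @param noise_sigma Additive Gaussian pixel-noise sigma (8-bit units).
#' @param seed Integer RNG seed used when rendering noise.
#' @return An object of class `nb_scene`.
#' @export
synthetic_scene <- function(tip_rest_positions,
                            frame_h = 240, frame_w = 320,
                            fps = 30, duration = 10,
                            deflection_direction = c(1, 0),
                            tip_sigma = 2, tip_intensity = 200,
                            shaft_intensity = 60, shaft_width = 1.2,
                            shaft_length = 60,
                            background = 20, noise_sigma = 0, seed = 1L) {
  pos <- as.matrix(as.data.frame(tip_rest_positions))
  if (ncol(pos) != 2) abort("`tip_rest_positions` needs two columns (x, y).")
  colnames(pos) <- c("x", "y")
  n <- nrow(pos)
  dir <- deflection_direction
  if (is.null(dim(dir))) dir <- matrix(rep(dir, length.out = 2 * n),
                                       ncol = 2, byrow = TRUE)
  dir <- dir / sqrt(rowSums(dir^2))
  if (round(duration * fps) < 2) {
    abort("scene must span at least 2 frames (duration * fps >= 2).")
  }
  structure(
    list(n_needles = n, tip_rest_positions = pos,
         deflection_direction = dir, frame_h = frame_h, frame_w = frame_w,
         fps = fps, duration = duration, tip_sigma = tip_sigma,
         tip_intensity = tip_intensity, shaft_intensity = shaft_intensity,
         shaft_width = shaft_width, shaft_length = shaft_length,
         background = background, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "nb_scene"
  )
}

# add a Gaussian blob to `frame` in place-ish (returns modified frame)
add_blob <- function(frame, cx, cy, sigma, intensity, radius = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  r <- if (is.null(radius)) ceiling(4 * sigma) else radius
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  if (length(rows) == 0 || length(cols) == 0) return(frame)
  gy <- exp(-(rows - cy)^2 / (2 * sigma^2))
  gx <- exp(-(cols - cx)^2 / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + intensity * outer(gy, gx)
  frame
}

# add a Gaussian ridge along segment p0 -> p1 (perpendicular profile)
add_ridge <- function(frame, p0, p1, sigma, intensity) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(3 * sigma)
  rows <- max(1, floor(min(p0[2], p1[2]) - r)):
    min(h, ceiling(max(p0[2], p1[2]) + r))
  cols <- max(1, floor(min(p0[1], p1[1]) - r)):
    min(w, ceiling(max(p0[1], p1[1]) + r))
  if (length(rows) == 0 || length(cols) == 0) return(frame)
  X <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(rows, length(rows), length(cols))
  v <- p1 - p0
  len2 <- sum(v^2)
  # projection parameter clamped to the segment
  tt <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2]) / len2
  tt <- pmax(pmin(tt, 1), 0)
  dx <- X - (p0[1] + tt * v[1])
  dy <- Y - (p0[2] + tt * v[2])
  frame[rows, cols] <- frame[rows, cols] +
    intensity * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  frame
}

#' Render a synthetic recording of a needle-array scene
#'
#' Draws, for every frame, each needle as a dim shaft ridge plus a Gaussian
#' tip blob displaced from its rest position along the needle's deflection
#' direction by the trace value at that frame, then adds Gaussian pixel noise
#' and quantises to 8 bits. Deterministic given the scene seed.
#'
#' The scene must keep tips separated by more than four times the maximum
#' deflection so tracker identities cannot swap by construction; violating
#' that, or deflecting a tip out of frame, is an error.
#'
#' @param traces A trace tibble (needle_id, frame, time_s, displacement_px)
#'   covering every needle of the scene, or a list of `nb_simulation`
#'   objects / trace tibbles.
#' @param scene A [synthetic_scene()].
#' @return A [frame_stack()] with the scene's fps.
#' @export
render_frames <- function(traces, scene) {
  stopifnot(inherits(scene, "nb_scene"))
  tr <- collect_traces(traces)
  check_columns(tr, trace_cols, "traces")
  ids <- sort(unique(tr$needle_id))
  if (length(ids) != scene$n_needles) {
    abort(sprintf("traces cover %d needle(s) but the scene has %d.",
                  length(ids), scene$n_needles))
  }
  nf <- round(scene$duration * scene$fps)
  dmat <- matrix(NA_real_, nrow = nf, ncol = scene$n_needles)
  for (k in seq_along(ids)) {
    dk <- tr$displacement_px[tr$needle_id == ids[k]][seq_len(nf)]
    if (length(dk) != nf || anyNA(dk)) {
      abort("each trace must have duration * fps displacement samples.")
    }
    dmat[, k] <- dk
  }
  dmax <- max(dmat)
  pos <- scene$tip_rest_positions
  if (scene$n_needles > 1) {
    dd <- as.matrix(stats::dist(pos))
    diag(dd) <- Inf
    if (min(dd) <= 4 * dmax) {
      abort(sprintf(
        "tips only %.1f px apart but max deflection is %.1f px; require separation > 4x deflection.",
        min(dd), dmax), class = "needlebeat_scene_misconfigured")
    }
  }
  # bounds check at maximal deflection
  tip_ext <- pos + scene$deflection_direction * dmax
  m <- 2 * scene$tip_sigma
  if (any(tip_ext[, 1] < 1 + m | tip_ext[, 1] > scene$frame_w - m |
          tip_ext[, 2] < 1 + m | tip_ext[, 2] > scene$frame_h - m |
          pos[, 1] < 1 + m | pos[, 1] > scene$frame_w - m |
          pos[, 2] < 1 + m | pos[, 2] > scene$frame_h - m)) {
    abort("a tip is displaced outside the frame bounds.",
          class = "needlebeat_scene_misconfigured")
  }
  frames <- with_seed(scene$seed, {
    lapply(seq_len(nf), function(f) {
      fr <- matrix(scene$background, scene$frame_h, scene$frame_w)
      for (k in seq_len(scene$n_needles)) {
        tip <- pos[k, ] + scene$deflection_direction[k, ] * dmat[f, k]
        base <- pos[k, ] + c(0, scene$shaft_length)
        # shaft: Gaussian ridge along the base-to-tip segment, stopping
        # 3 tip sigmas short of the blob so the tip stays blob-dominated
        seg <- tip - base
        seg_len <- sqrt(sum(seg^2))
        stop_at <- max(seg_len - 3 * scene$tip_sigma, 0)
        if (stop_at > 0) {
          fr <- add_ridge(fr, base, base + seg / seg_len * stop_at,
                          scene$shaft_width, scene$shaft_intensity)
        }
        fr <- add_blob(fr, tip[1], tip[2], scene$tip_sigma,
                       scene$tip_intensity)
      }
      if (scene$noise_sigma > 0) {
        fr <- fr + matrix(rnorm(length(fr), 0, scene$noise_sigma),
                          nrow(fr), ncol(fr))
      }
      round(pmax(pmin(fr, 255), 0))
    })
  })
  frame_stack(frames, fps = scene$fps)
}

# accept a trace tibble, an nb_simulation, or a list of either
collect_traces <- function(traces) {
  if (inherits(traces, "nb_simulation")) return(traces$trace)
  if (is.data.frame(traces)) return(as_tibble(traces))
  if (is.list(traces)) {
    parts <- lapply(traces, function(x) {
      if (inherits(x, "nb_simulation")) x$trace else as_tibble(x)
    })
    return(bind_rows(parts))
  }
  abort("`traces` must be a trace tibble, an nb_simulation, or a list of them.")
}
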