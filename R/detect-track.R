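#' Tip detection and tracking configuration
#'
#' @param mode `"seeded-template"` (default): normalized cross-correlation of
#'   reference-frame templates, sub-pixel peak by 2-D parabolic fit; or
#'   `"auto-blob"`: threshold bright blobs and take intensity-weighted
#'   centroids (unattended operation, no seeds needed).
#' @param template_half_size Template half-width, px (>= 2); the template is
#'   a `(2h+1) x (2h+1)` patch.
#' @param search_radius Per-frame search radius around the previous accepted
#'   position, px (>= 1).
#' @param min_confidence Matches scoring below this are recorded as missing,
#'   never as a fabricated position. Confidence is the correlation peak
#'   (seeded) or the normalized blob peak intensity (auto), both in [0, 1].
#' @param subpixel Refine the correlation peak by a parabolic fit of its
#'   3x3 neighbourhood.
#' @param min_contrast Auto mode: minimum peak-above-background intensity for
#'   a frame to contain any detectable blob (8-bit units).
#' @return An object of class `nb_detection_config`.
#' @export
detection_config <- function(mode = c("seeded-template", "auto-blob"),
                             template_half_size = 8, search_radius = 12,
                             min_confidence = 0.5, subpixel = TRUE,
                             min_contrast = 20) {
  mode <- match.arg(mode)
  stopifnot(template_half_size >= 2, search_radius >= 1,
            min_confidence >= 0, min_confidence <= 1)
  structure(
    list(mode = mode, template_half_size = as.integer(template_half_size),
         search_radius = search_radius, min_confidence = min_confidence,
         subpixel = isTRUE(subpixel), min_contrast = min_contrast),
    class = "nb_detection_config"
  )
}

# intensity-weighted centroid of the blob core near (cx, cy): weights are
# taken above the half-peak level so the dim shaft cannot bias the centre
refine_centroid <- function(frame, cx, cy, half) {
  h <- nrow(frame); w <- ncol(frame)
  ci <- round(cy); cj <- round(cx)
  rows <- max(1, ci - half):min(h, ci + half)
  cols <- max(1, cj - half):min(w, cj + half)
  win <- frame[rows, cols, drop = FALSE]
  bg <- median(win)
  wts <- pmax(win - (bg + 0.5 * (max(win) - bg)), 0)
  tot <- sum(wts)
  if (tot <= 0) return(c(cx, cy))
  c(sum(rep(cols, each = length(rows)) * wts) / tot,
    sum(rep(rows, times = length(cols)) * wts) / tot)
}

# template patch centred on the integer pixel nearest (cx, cy), plus the
# sub-pixel offset of the true centre relative to that integer centre
extract_template <- function(frame, cx, cy, half) {
  ci <- round(cy); cj <- round(cx)
  h <- nrow(frame); w <- ncol(frame)
  if (ci - half < 1 || ci + half > h || cj - half < 1 || cj + half > w) {
    abort("template window extends beyond the frame; move the seed inward.")
  }
  list(patch = frame[(ci - half):(ci + half), (cj - half):(cj + half)],
       center = c(cj, ci), offset = c(cx - cj, cy - ci))
}

# 1-D parabolic sub-pixel offset from three samples around a peak
parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, off))
}

# zero-normalized cross-correlation of `tmpl$patch` against `frame` over
# integer offsets within `radius` (Euclidean) of integer anchor (ax, ay)
ncc_match <- function(frame, tmpl, ax, ay, radius, subpixel = TRUE) {
  half <- (nrow(tmpl$patch) - 1L) / 2L
  h <- nrow(frame); w <- ncol(frame)
  r <- floor(radius)
  tp <- tmpl$patch - mean(tmpl$patch)
  tss <- sqrt(sum(tp^2))
  if (tss == 0) return(list(x = NA_real_, y = NA_real_, score = 0))
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  npx <- length(tp)
  scores <- matrix(-Inf, 2 * r + 1, 2 * r + 1)  # [dy + r + 1, dx + r + 1]
  for (i in seq_len(nrow(offs))) {
    cj <- ax + offs$dx[i]; ci <- ay + offs$dy[i]
    if (ci - half < 1 || ci + half > h || cj - half < 1 || cj + half > w) next
    p <- frame[(ci - half):(ci + half), (cj - half):(cj + half)]
    pc <- p - sum(p) / npx
    pss <- sqrt(sum(pc^2))
    scores[offs$dy[i] + r + 1, offs$dx[i] + r + 1] <-
      if (pss == 0) 0 else sum(pc * tp) / (pss * tss)
  }
  if (!any(is.finite(scores))) return(list(x = NA_real_, y = NA_real_, score = 0))
  best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
  bi <- best[1]; bj <- best[2]
  sx <- sy <- 0
  if (subpixel) {
    if (bj > 1 && bj < ncol(scores) &&
        is.finite(scores[bi, bj - 1]) && is.finite(scores[bi, bj + 1])) {
      sx <- parabolic_offset(scores[bi, bj - 1], scores[bi, bj],
                             scores[bi, bj + 1])
    }
    if (bi > 1 && bi < nrow(scores) &&
        is.finite(scores[bi - 1, bj]) && is.finite(scores[bi + 1, bj])) {
      sy <- parabolic_offset(scores[bi - 1, bj], scores[bi, bj],
                             scores[bi + 1, bj])
    }
  }
  list(x = ax + (bj - r - 1) + sx + tmpl$offset[1],
       y = ay + (bi - r - 1) + sy + tmpl$offset[2],
       score = max(0, min(1, max(scores[is.finite(scores)]))))
}

#' Detect needle tips in a single frame
#'
#' Seeded mode refines each user-supplied seed to a sub-pixel position by a
#' background-subtracted intensity-weighted centroid and reports the
#' normalized-cross-correlation self-match confidence. Auto mode thresholds
#' bright blobs above background, labels connected components and reports
#' each blob's intensity-weighted centroid, ordered left-to-right then
#' top-to-bottom.
#'
#' @param frame A 2-D intensity matrix (8-bit scale).
#' @param config A [detection_config()].
#' @param seeds Seeded mode: data frame / matrix of approximate tip
#'   positions, columns (x, y), one row per needle.
#' @return A tibble with columns `needle_id`, `x_px`, `y_px`, `confidence`.
#'   A blank frame in auto mode yields zero rows.
#' @export
detect_tips <- function(frame, config = detection_config(), seeds = NULL) {
  stopifnot(is.matrix(frame))
  if (config$mode == "seeded-template") {
    if (is.null(seeds) || nrow(as.data.frame(seeds)) == 0) {
      abort("seeded-template mode requires one seed per needle.")
    }
    s <- as.matrix(as.data.frame(seeds))
    out <- lapply(seq_len(nrow(s)), function(k) {
      p <- refine_centroid(frame, s[k, 1], s[k, 2], config$template_half_size)
      tibble(needle_id = k, x_px = p[1], y_px = p[2], confidence = 1)
    })
    bind_rows(out)
  } else {
    detect_blobs(frame, config)
  }
}

detect_blobs <- function(frame, config) {
  bg <- median(frame)
  peak <- max(frame)
  empty <- tibble(needle_id = integer(), x_px = double(),
                  y_px = double(), confidence = double())
  if (peak - bg < config$min_contrast) return(empty)
  mask <- frame >= bg + 0.5 * (peak - bg)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(lab)), 0)
  rows <- row(frame); cols <- col(frame)
  out <- lapply(ids, function(id) {
    sel <- lab == id
    if (sum(sel) < 3) return(NULL)
    wts <- pmax(frame[sel] - bg, 0)
    if (sum(wts) == 0) return(NULL)
    tibble(x_px = sum(cols[sel] * wts) / sum(wts),
           y_px = sum(rows[sel] * wts) / sum(wts),
           confidence = (max(frame[sel]) - bg) / (peak - bg))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out <- arrange(out, .data$x_px, .data$y_px)
  out <- filter(out, .data$confidence >= config$min_confidence)
  mutate(out, needle_id = dplyr::row_number(), .before = 1)
}

#' Track needle tips across a recording
#'
#' Frame 0 establishes each needle's reference position (and, in seeded
#' mode, its correlation template). Every subsequent frame is searched
#' within `search_radius` of the previous accepted position; a match below
#' `min_confidence` is recorded as missing and does not advance the search
#' centre. Identity is purely positional -- valid because scene separation
#' far exceeds deflection -- and consecutive accepted positions can never
#' differ by more than the search radius.
#'
#' @param stack A [frame_stack()].
#' @param config A [detection_config()].
#' @param seeds Approximate tip positions on frame 0 (seeded mode); in auto
#'   mode, seeds are taken from auto-detection on frame 0.
#' @return A tracks tibble: `needle_id`, `frame` (0-based), `time_s`,
#'   `x_px`, `y_px`, `confidence`, `missing` (0/1). Needles missing in more
#'   than 25% of frames carry a tracking-quality warning, also stored in
#'   `attr(, "quality")`.
#' @export
track <- function(stack, config = detection_config(), seeds = NULL) {
  stopifnot(inherits(stack, "nb_frame_stack"))
  ref <- stack$frames[[1]]
  if (is.null(seeds)) {
    det <- detect_blobs(ref, config)
    if (nrow(det) == 0) abort("no tips detected on the reference frame.")
    seeds <- det[, c("x_px", "y_px")]
  }
  s <- as.matrix(as.data.frame(seeds))
  nf <- n_frames(stack)
  n <- nrow(s)
  half <- config$template_half_size
  tracks <- vector("list", n)
  quality <- vector("list", n)
  for (k in seq_len(n)) {
    p0 <- refine_centroid(ref, s[k, 1], s[k, 2], half)
    tmpl <- extract_template(ref, p0[1], p0[2], half)
    xs <- ys <- conf <- rep(NA_real_, nf)
    miss <- rep(1L, nf)
    xs[1] <- p0[1]; ys[1] <- p0[2]; conf[1] <- 1; miss[1] <- 0L
    anchor <- tmpl$center  # integer (x, y) search centre in match space
    prev <- p0
    for (f in 2:nf) {
      m <- ncc_match(stack$frames[[f]], tmpl, anchor[1], anchor[2],
                     config$search_radius, config$subpixel)
      if (is.na(m$x) || m$score < config$min_confidence) {
        conf[f] <- m$score
        next  # missing: search centre does not advance
      }
      # bound consecutive motion by the search radius exactly
      step <- c(m$x, m$y) - prev
      sl <- sqrt(sum(step^2))
      if (sl > config$search_radius) {
        step <- step * config$search_radius / sl
        m$x <- prev[1] + step[1]; m$y <- prev[2] + step[2]
      }
      xs[f] <- m$x; ys[f] <- m$y; conf[f] <- m$score; miss[f] <- 0L
      prev <- c(m$x, m$y)
      anchor <- round(prev - tmpl$offset)
    }
    frac_missing <- mean(miss == 1L)
    warn_msg <- NA_character_
    if (frac_missing > 0.25) {
      warn_msg <- sprintf("needle %d missing in %.0f%% of frames", k,
                          100 * frac_missing)
      warn(paste0("tracking quality: ", warn_msg))
    }
    quality[[k]] <- tibble(needle_id = k, missing_frac = frac_missing,
                           warning = warn_msg)
    tracks[[k]] <- tibble(
      needle_id = k, frame = seq_len(nf) - 1L,
      time_s = (seq_len(nf) - 1L) / stack$fps,
      x_px = xs, y_px = ys,
      confidence = ifelse(is.na(conf), 0, conf), missing = miss
    )
  }
  out <- bind_rows(tracks)
  attr(out, "quality") <- bind_rows(quality)
  attr(out, "fps") <- stack$fps
  out
}

#' Convert tip tracks to displacement traces
#'
#' Estimates each needle's rest position, then reports per-frame Euclidean
#' distance from it (hence displacement is always >= 0). The rest position
#' is re-estimated from low-motion frames: a first pass measures distance
#' from the frame-0 position, and the reference is the coordinate-wise
#' median over the lowest-decile-displacement frames -- robust to recordings
#' that begin mid-beat. Missing frames propagate as missing (`NA`).
#'
#' @param tracks A tracks tibble from [track()].
#' @param rest_quantile Fraction of lowest-displacement frames used to
#'   re-estimate the rest position (default 0.1).
#' @return A trace tibble: `needle_id`, `frame`, `time_s`,
#'   `displacement_px`; rest positions in `attr(, "reference")`.
#' @export
to_displacement <- function(tracks, rest_quantile = 0.1) {
  check_columns(tracks, track_cols, "tracks")
  refs <- list(); out <- list()
  for (id in sort(unique(tracks$needle_id))) {
    tk <- tracks[tracks$needle_id == id, ]
    ok <- tk$missing == 0L & !is.na(tk$x_px)
    if (!any(ok)) {
      abort(sprintf("needle %d has no accepted positions.", id),
            class = "needlebeat_empty_trace")
    }
    x0 <- tk$x_px[ok][1]; y0 <- tk$y_px[ok][1]
    d0 <- sqrt((tk$x_px - x0)^2 + (tk$y_px - y0)^2)
    thr <- quantile(d0[ok], rest_quantile, na.rm = TRUE)
    low <- ok & d0 <= thr
    rx <- median(tk$x_px[low]); ry <- median(tk$y_px[low])
    d <- sqrt((tk$x_px - rx)^2 + (tk$y_px - ry)^2)
    refs[[length(refs) + 1]] <- tibble(needle_id = id, ref_x = rx, ref_y = ry)
    out[[length(out) + 1]] <- tibble(
      needle_id = id, frame = tk$frame, time_s = tk$time_s,
      displacement_px = d
    )
  }
  res <- bind_rows(out)
  attr(res, "reference") <- bind_rows(refs)
  attr(res, "fps") <- attr(tracks, "fps")
  res
}
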