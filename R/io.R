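#' Read a recording into a frame stack
#'
#' Accepts a multi-page TIFF file or a directory of PNG/TIFF frames (read
#' in lexicographic order). Colour frames are converted to grayscale
#' luminance. TIFF/PNG containers carry no frame-rate metadata, so `fps`
#' must be supplied. Compressed video containers (MP4/AVI) are not
#' supported.
#'
#' @param path A multi-page TIFF file or a directory of PNG/TIFF frames.
#' @param fps Frames per second of the recording (required).
#' @param pixel_size_um Optional micrometres per pixel.
#' @return A [frame_stack()] with intensities on the 8-bit (0--255) scale.
#' @export
read_frames <- function(path, fps = NULL, pixel_size_um = NULL) {
  if (is.null(fps)) {
    abort("`fps` is required: image containers carry no frame-rate metadata.",
          class = "needlebeat_missing_fps")
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      abort("no PNG/TIFF frames found in directory.",
            class = "needlebeat_empty_stack")
    }
    frames <- lapply(files, read_one_image)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, normalize_image)
  } else if (grepl("\\.(mp4|avi|mov)$", path, ignore.case = TRUE)) {
    abort("compressed video containers are not supported; export the recording as a multi-page TIFF or PNG sequence.",
          class = "needlebeat_unsupported_container")
  } else {
    abort("unreadable container: expected a TIFF stack or a frame directory.",
          class = "needlebeat_unsupported_container")
  }
  frame_stack(frames, fps = fps, pixel_size_um = pixel_size_um)
}

read_one_image <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  normalize_image(img)
}

# [0,1] (possibly colour) array -> grayscale matrix on the 0-255 scale
normalize_image <- function(img) {
  if (length(dim(img)) == 3) {
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  img * 255
}

#' Write a frame stack to disk
#'
#' @param stack A [frame_stack()].
#' @param path Output path: `.tif`/`.tiff` writes a multi-page TIFF; an
#'   existing or creatable directory writes a zero-padded PNG sequence.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "nb_frame_stack"))
  norm <- lapply(stack$frames, function(f) pmax(pmin(f / 255, 1), 0))
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm)) {
      png::writePNG(norm[[i]],
                    file.path(path, sprintf("frame_%05d.png", i - 1L)))
    }
  }
  invisible(path)
}

#' Tabular readers/writers
#'
#' CSV is the canonical tabular interchange format: tracks
#' (`needle_id, frame, time_s, x_px, y_px, confidence, missing`), traces
#' (`needle_id, frame, time_s, displacement_px`) and beats
#' (`needle_id, onset_s, peak_s, relax_s, amplitude_px`). Frame indices are
#' 0-based and times are in seconds throughout.
#'
#' @param x The tibble to write.
#' @param path CSV path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
write_tracks <- function(x, path) {
  check_columns(x, track_cols, "tracks")
  readr::write_csv(x[, track_cols], path)
  invisible(path)
}

#' @rdname tabular-io
#' @export
read_tracks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           needle_id = "i", frame = "i", missing = "i",
                           .default = "d"))
  check_columns(out, track_cols, "tracks")
  out
}

#' @rdname tabular-io
#' @export
write_beats <- function(x, path) {
  check_columns(x, beat_cols, "beats")
  readr::write_csv(x[, beat_cols], path)
  invisible(path)
}

#' @rdname tabular-io
#' @export
read_beats <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(needle_id = "i",
                                                 .default = "d"))
  check_columns(out, beat_cols, "beats")
  out
}

#' @rdname tabular-io
#' @export
write_traces <- function(x, path) {
  check_columns(x, trace_cols, "traces")
  readr::write_csv(x[, trace_cols], path)
  invisible(path)
}

#' @rdname tabular-io
#' @export
read_traces <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(needle_id = "i",
                                                 frame = "i",
                                                 .default = "d"))
  check_columns(out, trace_cols, "traces")
  out
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: read (or accept) a frame stack, track the
#' seeded tips, convert to displacement, detect beats and summarise, and --
#' when a protocol with per-event observation windows is given -- build the
#' baseline-normalized time course. Writes `tracks.csv`, `traces.csv`,
#' `beats.csv`, `summary.json`, optionally `timecourse.csv`, and a run
#' manifest (`manifest.json` with config hash, seed and package version).
#' Re-running with an identical config reproduces identical CSV content; a
#' failed stage leaves a manifest marking where the run stopped.
#'
#' @param input A [frame_stack()] or a path readable by [read_frames()].
#' @param seeds Tip seed positions on frame 0 (data frame with x, y).
#' @param out_dir Output directory (created if needed).
#' @param fps Frames per second (required for path input).
#' @param detection A [detection_config()].
#' @param beat A [beat_config()].
#' @param protocol Optional protocol tibble (see [read_protocol()]) whose
#'   events carry `window_start`/`window_end` observation windows.
#' @param seed Integer seed recorded in the manifest.
#' @return A list with `summary` (nb_summary), `timecourse` (or NULL) and
#'   `manifest`, invisibly; artifacts are on disk in `out_dir`.
#' @export
pipeline_run <- function(input, seeds, out_dir, fps = NULL,
                         detection = detection_config(),
                         beat = beat_config(), protocol = NULL,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(fps = fps, seeds = as.data.frame(seeds),
              detection = unclass(detection), beat = unclass(beat),
              protocol = if (is.null(protocol)) NULL
                         else as.data.frame(protocol),
              seed = as.integer(seed))
  manifest <- list(
    package = "needlebeat",
    version = as.character(utils::packageVersion("needlebeat")),
    seed = as.integer(seed),
    config_hash = rlang::hash(cfg),
    stages = list()
  )
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(err)), parent = err)
  }
  stage <- function(name, expr) {
    tryCatch({
      res <- force(expr)
      manifest$stages[[name]] <<- list(status = "ok")
      res
    }, error = function(e) fail(name, e))
  }

  stack <- stage("read", {
    if (inherits(input, "nb_frame_stack")) input
    else read_frames(input, fps = fps)
  })
  tracks <- stage("track", track(stack, detection, seeds))
  traces <- stage("displacement", to_displacement(tracks))
  summary <- stage("analyze", {
    s <- summarize_contractions(traces, beat, fps = stack$fps)
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    write_traces(traces, file.path(out_dir, "traces.csv"))
    write_beats(s$beats, file.path(out_dir, "beats.csv"))
    jsonlite::write_json(
      list(per_needle = s$per_needle, sync_index = s$sync_index,
           window_s = s$window_s, fps = s$fps),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
    s
  })
  timecourse <- NULL
  if (!is.null(protocol) && nrow(protocol) > 0) {
    timecourse <- stage("response", {
      validate_protocol(protocol)
      tc <- timepoint_summaries(traces, summary$beats, protocol)
      tc <- normalize_to_baseline(tc)
      readr::write_csv(tc, file.path(out_dir, "timecourse.csv"))
      tc
    })
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, timecourse = timecourse,
                 manifest = manifest))
}

# per-protocol-event beat summaries over the event observation windows
timepoint_summaries <- function(traces, beats, protocol) {
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    ev <- protocol[i, ]
    w0 <- ev$window_start; w1 <- ev$window_end
    if (is.na(w0) || is.na(w1)) {
      abort(sprintf("event '%s' lacks an observation window.", ev$label))
    }
    b <- beats[beats$peak_s >= w0 & beats$peak_s < w1, ]
    tibble(
      label = ev$label, time_s = ev$time_s,
      beats_per_10s = nrow(b) * 10 / (w1 - w0) /
        max(1, length(unique(traces$needle_id))),
      mean_amplitude_px = if (nrow(b)) mean(b$amplitude_px) else NA_real_
    )
  })
  bind_rows(rows)
}
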