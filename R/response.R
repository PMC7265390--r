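#' Read a drug/condition protocol
#'
#' A protocol is an ordered set of events -- exactly one `baseline` first,
#' then drug additions, washouts or observation timepoints -- each with a
#' time (seconds; `time_h` is accepted and converted at the boundary) and
#' optionally a drug name, concentration, and an observation window
#' (`window_start`/`window_end`, s) into the recording.
#'
#' @param path Path to a YAML file with a top-level `events` list.
#' @return A protocol tibble: `label`, `time_s`, `drug`, `concentration`,
#'   `window_start`, `window_end`.
#' @export
read_protocol <- function(path) {
  raw <- yaml::read_yaml(path)
  events <- if (!is.null(raw$events)) raw$events else raw
  rows <- lapply(events, function(e) {
    time_s <- if (!is.null(e$time_h)) e$time_h * 3600 else e$time_s
    tibble(
      label = e$label,
      time_s = as.numeric(time_s),
      drug = e$drug %||% NA_character_,
      concentration = e$concentration %||% NA_character_,
      window_start = as.numeric(e$window_start %||% NA),
      window_end = as.numeric(e$window_end %||% NA)
    )
  })
  out <- bind_rows(rows)
  validate_protocol(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_protocol <- function(events) {
  check_columns(events, c("label", "time_s"), "protocol")
  if (is.unsorted(events$time_s)) {
    abort("protocol events must be time-ordered.")
  }
  if (sum(events$label == "baseline") != 1 ||
      events$label[1] != "baseline") {
    abort("protocol needs exactly one baseline event, first in order.")
  }
  events
}

#' Normalize a condition time course to its baseline
#'
#' Reproduces the study's calculation: per-timepoint mean tip-movement
#' amplitude divided by the pre-drug (baseline) amplitude, with beating
#' rate carried through unnormalized. A timepoint with no beats (e.g. a
#' late cardiotoxicity endpoint where contraction has ceased) maps to
#' normalized amplitude 0.
#'
#' @param summaries Tibble with one row per timepoint: `label`, `time_s`,
#'   `beats_per_10s`, `mean_amplitude_px` (`NA` or 0 beats allowed at
#'   non-baseline timepoints).
#' @param baseline Label of the baseline timepoint (default "baseline").
#' @return A `nb_timecourse` tibble: input columns plus
#'   `normalized_amplitude`, with the baseline row at exactly 1.
#' @export
normalize_to_baseline <- function(summaries, baseline = "baseline") {
  check_columns(summaries,
                c("label", "time_s", "beats_per_10s", "mean_amplitude_px"),
                "summaries")
  base <- summaries[summaries$label == baseline, ]
  if (nrow(base) != 1) {
    abort(sprintf("expected exactly one '%s' timepoint.", baseline))
  }
  b <- base$mean_amplitude_px
  if (is.na(b) || !is.finite(b) || b <= 0) {
    abort("baseline amplitude is zero or absent; normalization undefined.",
          class = "needlebeat_normalization_undefined")
  }
  out <- summaries %>%
    mutate(normalized_amplitude = ifelse(
      is.na(.data$mean_amplitude_px), 0, .data$mean_amplitude_px / b
    ))
  class(out) <- c("nb_timecourse", class(tibble()))
  out
}

#' Washout recovery decision
#'
#' A time course has recovered when any timepoint at or after the washout
#' event returns within `band` of the baseline level (normalized amplitude
#' within `1 +/- band`).
#'
#' @param timecourse A `nb_timecourse` from [normalize_to_baseline()].
#' @param band Recovery band around 1 (default 0.2, i.e. within 20% of
#'   baseline).
#' @param washout_label Label of the washout event (default any label
#'   containing "washout").
#' @return A one-row tibble: `recovered` (logical), `recovery_time_s`
#'   (`NA` when not recovered).
#' @export
washout_recovery <- function(timecourse, band = 0.2,
                             washout_label = "washout") {
  check_columns(timecourse, c("label", "time_s", "normalized_amplitude"),
                "timecourse")
  wo <- grepl(washout_label, timecourse$label, fixed = TRUE)
  if (!any(wo)) abort("time course contains no washout event.")
  t_wo <- min(timecourse$time_s[wo])
  post <- timecourse[timecourse$time_s >= t_wo, ]
  hit <- abs(post$normalized_amplitude - 1) <= band
  tibble(
    recovered = any(hit),
    recovery_time_s = if (any(hit)) min(post$time_s[hit]) else NA_real_
  )
}

#' Two-group comparison by Student's t-test
#'
#' Classical two-sided pooled-variance t-test, the comparison used for the
#' construct measurements, with significance flags at the 0.05 and 0.01
#' levels. Degenerate zero-variance input does not crash: identical means
#' give p = 1, separated means p = 0. Welch's correction is available
#' behind a flag.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance test instead (default FALSE).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `significant_05`, `significant_01`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
               parameter = length(a) + length(b) - 2,
               p.value = if (eq) 1 else 0)
  } else {
    ht <- t.test(a, b, var.equal = !welch)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  tibble(
    statistic = tt$statistic, df = tt$parameter, p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b),
    significant_05 = tt$p.value < 0.05,
    significant_01 = tt$p.value < 0.01
  )
}

#' Convert tip deflection to an end-load force (optional utility)
#'
#' Euler--Bernoulli cantilever with an end load: `F = 3 E I delta / L^3`
#' with second moment `I = pi d^4 / 64`. All needle properties must be
#' supplied by the user; measuring them is outside what video analysis can
#' provide, so when any is missing the conversion is refused rather than
#' guessed. The result is a model-based estimate and is never part of the
#' default outputs.
#'
#' @param deflection Tip deflection; pixels by default, or micrometres with
#'   `input_unit = "um"`.
#' @param youngs_modulus Needle Young's modulus, Pa.
#' @param diameter Needle diameter, m.
#' @param free_length Needle free length, m.
#' @param pixel_size_um Micrometres per pixel (required for pixel input).
#' @param input_unit `"px"` (default) or `"um"`.
#' @return Force in newtons (numeric, same length as `deflection`).
#' @export
force_from_deflection <- function(deflection, youngs_modulus = NULL,
                                  diameter = NULL, free_length = NULL,
                                  pixel_size_um = NULL,
                                  input_unit = c("px", "um")) {
  input_unit <- match.arg(input_unit)
  need <- list(youngs_modulus = youngs_modulus, diameter = diameter,
               free_length = free_length)
  if (input_unit == "px") need["pixel_size_um"] <- list(pixel_size_um)
  missing <- names(need)[vapply(need, function(v)
    is.null(v) || !is.finite(v), logical(1))]
  if (length(missing) > 0) {
    abort(paste0("force unavailable: missing needle propert",
                 if (length(missing) > 1) "ies: " else "y: ",
                 paste(missing, collapse = ", ")),
          class = "needlebeat_force_unavailable")
  }
  delta_um <- if (input_unit == "px") deflection * pixel_size_um else deflection
  delta_m <- delta_um * 1e-6
  I <- pi * diameter^4 / 64
  3 * youngs_modulus * I * delta_m / free_length^3
}
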