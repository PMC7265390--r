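test_that("flat traces yield no beats without erroring", {
  flat <- simulate_trace(twitch_model(rate = 0), 10, 30, seed = 1)
  b <- detect_beats(flat$trace, fps = 30)
  expect_identical(nrow(b), 0L)
  r <- beating_rate(b)
  expect_equal(r$beats_per_10s, 0)
})

test_that("paced and spontaneous traces are counted at the condition rates", {
  # 2 Hz pacing over 10 s -> 20 beats despite incomplete relaxation
  sim2 <- simulate_trace(twitch_model(protocol = pulse_schedule(2, 10)),
                         10, 30, seed = 1)
  noisy <- sim2$trace
  set.seed(4)
  noisy$displacement_px <- pmax(noisy$displacement_px + rnorm(300, 0, 0.15), 0)
  expect_identical(nrow(detect_beats(noisy, fps = 30)), 20L)
  # 0.6 Hz spontaneous -> 6 beats per 10 s
  sim6 <- simulate_trace(twitch_model(rate = 0.6), 10, 30, seed = 3)
  b6 <- detect_beats(sim6$trace, fps = 30)
  expect_identical(nrow(b6), nrow(sim6$beats))
  expect_equal(beating_rate(b6)$beats_per_10s, 6)
})

test_that("beating rate rescales counts to a 10 s window", {
  beats <- tibble::tibble(needle_id = 1L, onset_s = 0:9, peak_s = 0:9 + 0.1,
                          relax_s = 0:9 + 0.3, amplitude_px = 8)
  expect_equal(beating_rate(beats, c(0, 10))$beats_per_10s, 10)
  expect_equal(beating_rate(beats[beats$peak_s < 5, ][1:3, ],
                            c(0, 5))$beats_per_10s, 6)
  expect_equal(beating_rate(beats[0, ])$beats_per_10s, 0)
})

test_that("amplitude summaries report mean and CV per needle", {
  beats <- tibble::tibble(needle_id = 1L, onset_s = c(0, 1, 2),
                          peak_s = c(0.1, 1.1, 2.1),
                          relax_s = c(0.4, 1.4, 2.4), amplitude_px = c(8, 8, 8))
  s <- amplitude_summary(beats)
  expect_equal(s$mean_amplitude_px, 8)
  expect_equal(s$amplitude_cv, 0)
  expect_error(amplitude_summary(beats[0, ]), class = "needlebeat_no_beats")
})

test_that("recovered amplitude tracks the true twitch amplitude", {
  sim <- simulate_trace(twitch_model(rate = 0.6, amplitude = 8), 10, 30,
                        seed = 3)
  b <- detect_beats(sim$trace, fps = 30)
  expect_equal(mean(b$amplitude_px), 8, tolerance = 0.1)
  # monotone in the true amplitude at fixed noise
  rec <- vapply(c(2, 4, 8, 16), function(a) {
    s <- simulate_trace(twitch_model(rate = 0.8, amplitude = a), 10, 30,
                        seed = 11)
    tr <- s$trace
    set.seed(5)
    tr$displacement_px <- pmax(tr$displacement_px + rnorm(300, 0, 0.1), 0)
    mean(detect_beats(tr, fps = 30)$amplitude_px)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("2 Hz pacing reduces per-beat amplitude relative to 1 Hz", {
  m1 <- twitch_model(protocol = pulse_schedule(1, 10))
  m2 <- twitch_model(protocol = pulse_schedule(2, 10))
  a1 <- mean(detect_beats(simulate_trace(m1, 10, 30, seed = 1)$trace,
                          fps = 30)$amplitude_px)
  a2 <- mean(detect_beats(simulate_trace(m2, 10, 30, seed = 1)$trace,
                          fps = 30)$amplitude_px)
  expect_lt(a2, a1)
})

test_that("no two detected peaks violate the refractory separation", {
  cfg <- beat_config()
  for (sd_seed in 1:5) {
    sim <- simulate_trace(twitch_model(rate = 2), 10, 30, seed = sd_seed)
    tr <- sim$trace
    set.seed(sd_seed)
    tr$displacement_px <- pmax(tr$displacement_px + rnorm(300, 0, 0.2), 0)
    b <- detect_beats(tr, fps = 30, config = cfg)
    if (nrow(b) > 1) {
      expect_true(all(diff(b$peak_s) >= cfg$min_interbeat - 1e-9))
    }
  }
})

test_that("beat counts are frame-rate invariant up to 2 Hz", {
  for (r in c(0.6, 1, 2)) {
    n30 <- nrow(detect_beats(
      simulate_trace(twitch_model(rate = r), 10, 30, seed = 5)$trace,
      fps = 30))
    n60 <- nrow(detect_beats(
      simulate_trace(twitch_model(rate = r), 10, 60, seed = 5)$trace,
      fps = 60))
    expect_identical(n30, n60)
  }
})

test_that("sync index is 1 for co-occurring beats and < 1 for mixed rates", {
  same <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(needle_id = i, onset_s = 0:7, peak_s = 0:7 + 0.11,
                   relax_s = 0:7 + 0.4, amplitude_px = 8)
  }))
  expect_equal(sync_index(same), 1)
  mixed <- dplyr::bind_rows(lapply(1:4, function(i) {
    f <- c(1, 1, 0.8, 0.8)[i]
    ph <- c(0.12, 0.55, 0.31, 0.97)[i]
    pk <- seq(ph, 10, by = 1 / f)
    tibble::tibble(needle_id = i, onset_s = pk - 0.1, peak_s = pk,
                   relax_s = pk + 0.3, amplitude_px = 8)
  }))
  expect_lt(sync_index(mixed), 1)
  # with infinite tolerance every beat matches
  expect_equal(sync_index(mixed, tolerance = Inf), 1)
  # a beat-free needle contributes zero to its pairs
  expect_lt(sync_index(same[same$needle_id < 4, ], needle_ids = 1:4),
            sync_index(same[same$needle_id < 4, ], needle_ids = 1:3))
  expect_error(sync_index(same[same$needle_id == 1, ]), "two needles")
})

test_that("windowed summaries report per-needle rates and sync", {
  sims <- lapply(1:2, function(i) {
    simulate_trace(twitch_model(rate = c(1, 0.8)[i]), 10, 30,
                   seed = i, needle_id = i)
  })
  traces <- dplyr::bind_rows(lapply(sims, function(s) s$trace))
  s <- summarize_contractions(traces, fps = 30)
  expect_equal(nrow(s$per_needle), 2)
  expect_equal(s$per_needle$n_beats,
               vapply(sims, function(x) nrow(x$beats), integer(1)))
  expect_true(s$sync_index >= 0 && s$sync_index <= 1)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  g <- glance(s)
  expect_equal(g$n_needles, 2)
  # single flat trace: rate 0, no sync index
  flat <- simulate_trace(twitch_model(rate = 0), 10, 30, seed = 1)
  sf <- summarize_contractions(flat$trace, fps = 30)
  expect_equal(sf$per_needle$beats_per_10s, 0)
  expect_true(is.na(sf$sync_index))
  # mismatched lengths signal an alignment error
  bad <- dplyr::bind_rows(sims[[1]]$trace, sims[[2]]$trace[1:200, ])
  expect_error(summarize_contractions(bad, fps = 30),
               class = "needlebeat_alignment_error")
})

test_that("short missing gaps are bridged, long gaps split the trace", {
  sim <- simulate_trace(twitch_model(rate = 0.8), 10, 30, seed = 2)
  tr <- sim$trace
  n_clean <- nrow(detect_beats(tr, fps = 30))
  # a 2-frame gap away from any peak is interpolated through
  gap_at <- which(tr$displacement_px < 0.2)[50]
  tr2 <- tr
  tr2$displacement_px[gap_at + 0:1] <- NA
  expect_identical(nrow(detect_beats(tr2, fps = 30)), n_clean)
  # a long gap splits into independent segments, both still analysed
  tr3 <- tr
  tr3$displacement_px[150:170] <- NA
  b3 <- detect_beats(tr3, fps = 30)
  expect_gt(nrow(b3), 0)
  expect_true(all(b3$peak_s < 149 / 30 | b3$peak_s > 170 / 30))
})
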