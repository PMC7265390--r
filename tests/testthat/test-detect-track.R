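test_that("auto-blob detection is sub-pixel accurate and ignores blank frames", {
  scene <- synthetic_scene(data.frame(x = 100.4, y = 50), noise_sigma = 0,
                           duration = 0.1, fps = 30)
  trc <- tibble::tibble(needle_id = 1L, frame = 0:2, time_s = (0:2) / 30,
                        displacement_px = 0)
  st <- render_frames(trc, scene)
  det <- detect_tips(st$frames[[1]], detection_config(mode = "auto-blob"))
  expect_lt(abs(det$x_px - 100.4), 0.25)
  expect_lt(abs(det$y_px - 50.0), 0.25)
  blank <- matrix(17, 240, 320)
  expect_identical(
    nrow(detect_tips(blank, detection_config(mode = "auto-blob"))), 0L
  )
})

test_that("nearby seeds resolve to their own tips with stable identities", {
  scene <- synthetic_scene(data.frame(x = c(100, 160), y = c(60, 60)),
                           noise_sigma = 0, duration = 0.1, fps = 30)
  trc <- dplyr::bind_rows(
    tibble::tibble(needle_id = 1L, frame = 0:2, time_s = (0:2) / 30,
                   displacement_px = 0),
    tibble::tibble(needle_id = 2L, frame = 0:2, time_s = (0:2) / 30,
                   displacement_px = 0)
  )
  st <- render_frames(trc, scene)
  det <- detect_tips(st$frames[[1]], detection_config(),
                     seeds = data.frame(x = c(103, 157), y = c(62, 58)))
  expect_equal(det$needle_id, c(1, 2))
  expect_lt(abs(det$x_px[1] - 100), 0.3)
  expect_lt(abs(det$x_px[2] - 160), 0.3)
})

test_that("a static scene tracks as constant positions at the reference", {
  flat <- simulate_trace(twitch_model(rate = 0), 1, 30, seed = 1)
  st <- render_frames(flat, single_needle_scene(0, 3, duration = 1))
  tk <- track(st, detection_config(), seeds = data.frame(x = 100, y = 80))
  expect_true(all(tk$missing == 0))
  expect_lt(diff(range(tk$x_px)), 0.1)
  expect_lt(diff(range(tk$y_px)), 0.1)
  expect_lt(abs(mean(tk$x_px) - 100), 0.25)
})

test_that("tracking a known rendered trace recovers positions to < 0.3 px RMSE", {
  pl <- run_single_pipeline(
    twitch_model(protocol = pulse_schedule(0.8, 10)), noise_sigma = 0
  )
  truth_x <- 100 + pl$sim$trace$displacement_px  # deflection along +x
  err <- sqrt(mean((pl$tracks$x_px - truth_x)^2 + (pl$tracks$y_px - 80)^2))
  expect_lt(err, 0.3)
})

test_that("4-needle tracking keeps identities (no swaps)", {
  pos <- four_needle_positions()
  sims <- lapply(1:4, function(i) {
    f <- c(1, 1, 0.8, 0.8)[i]
    simulate_trace(twitch_model(protocol = pulse_schedule(f, 10)), 10, 30,
                   seed = i, needle_id = i, phase = c(0.1, 0.6, 0.3, 0.9)[i])
  })
  st <- render_frames(sims, synthetic_scene(pos, noise_sigma = 2, seed = 8))
  tk <- track(st, detection_config(), seeds = pos)
  mp <- dplyr::summarise(dplyr::group_by(tk, needle_id),
                         mx = mean(x_px), my = mean(y_px))
  # each track's mean position stays nearest its own rest position
  d <- as.matrix(dist(rbind(as.matrix(mp[, c("mx", "my")]),
                            as.matrix(pos))))[1:4, 5:8]
  expect_equal(unname(apply(d, 1, which.min)), 1:4)
  expect_true(all(diag(d) < 5))
})

test_that("seeded-template and auto-blob agree on noiseless renders", {
  scene <- synthetic_scene(data.frame(x = c(90.3, 200.7), y = c(70.2, 140.6)),
                           noise_sigma = 0, duration = 0.1, fps = 30)
  trc <- dplyr::bind_rows(lapply(1:2, function(i) {
    tibble::tibble(needle_id = i, frame = 0:2, time_s = (0:2) / 30,
                   displacement_px = 0)
  }))
  st <- render_frames(trc, scene)
  auto <- detect_tips(st$frames[[1]], detection_config(mode = "auto-blob"))
  seeded <- detect_tips(st$frames[[1]], detection_config(),
                        seeds = data.frame(x = c(90, 201), y = c(70, 141)))
  expect_lt(max(abs(auto$x_px - seeded$x_px)), 0.3)
  expect_lt(max(abs(auto$y_px - seeded$y_px)), 0.3)
})

test_that("position error degrades monotonically with pixel noise", {
  rmse <- vapply(c(0, 2, 5, 10), function(sig) {
    pl <- run_single_pipeline(
      twitch_model(protocol = pulse_schedule(1, 10)),
      noise_sigma = sig, scene_seed = 77, duration = 5
    )
    truth_x <- 100 + pl$sim$trace$displacement_px
    sqrt(mean((pl$tracks$x_px - truth_x)^2 + (pl$tracks$y_px - 80)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > -0.005))
  expect_lt(rmse[1], 0.3)
})

test_that("consecutive accepted positions never jump past the search radius", {
  cfg <- detection_config(search_radius = 12)
  pl <- run_single_pipeline(
    twitch_model(protocol = pulse_schedule(2, 10)),
    noise_sigma = 5, scene_seed = 31, duration = 5
  )
  tk <- pl$tracks[pl$tracks$missing == 0, ]
  steps <- sqrt(diff(tk$x_px)^2 + diff(tk$y_px)^2)
  expect_true(all(steps <= cfg$search_radius + 1e-9))
})

test_that("displacement conversion measures Euclidean distance from rest", {
  # constant track -> all-zero trace
  const <- tibble::tibble(needle_id = 1L, frame = 0:99,
                          time_s = (0:99) / 30, x_px = 50, y_px = 60,
                          confidence = 1, missing = 0L)
  tr <- to_displacement(const)
  expect_equal(tr$displacement_px, rep(0, 100))
  # +/- 5 px oscillation about rest along x peaks at 5 px
  osc <- const
  osc$x_px <- 50 + 5 * sin(2 * pi * (0:99) / 25)
  tro <- to_displacement(osc)
  expect_equal(max(tro$displacement_px), 5, tolerance = 0.05)
  # all-missing track signals an empty-trace error
  gone <- const
  gone$missing <- 1L
  gone$x_px <- NA_real_
  expect_error(to_displacement(gone), class = "needlebeat_empty_trace")
})

test_that("simulate-render-track-displacement round trip stays within 0.5 px", {
  pl <- run_single_pipeline(
    twitch_model(protocol = pulse_schedule(0.8, 10)), noise_sigma = 0
  )
  expect_lt(
    max(abs(pl$traces$displacement_px - pl$sim$trace$displacement_px)), 0.5
  )
})

test_that("missing detections are marked, never fabricated", {
  # blank the middle third of the recording so the tip vanishes
  flat <- simulate_trace(twitch_model(rate = 0), 2, 30, seed = 1)
  st <- render_frames(flat, single_needle_scene(0, 3, duration = 2))
  for (f in 21:40) st$frames[[f]] <- matrix(20, 240, 320)
  expect_warning(
    tk <- track(st, detection_config(), seeds = data.frame(x = 100, y = 80)),
    "tracking quality"
  )
  expect_true(all(tk$missing[21:40] == 1))
  expect_true(all(is.na(tk$x_px[tk$missing == 1])))
  expect_true(all(tk$missing[41:60] == 0))  # reacquired afterwards
})
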