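# shared fixture builders: everything is generated in code

single_needle_scene <- function(noise_sigma = 0, seed = 1L, duration = 10,
                                fps = 30, x = 100, y = 80) {
  synthetic_scene(data.frame(x = x, y = y), noise_sigma = noise_sigma,
                  seed = seed, duration = duration, fps = fps)
}

four_needle_positions <- function() {
  data.frame(x = c(80, 160, 240, 80), y = c(60, 60, 60, 150))
}

# simulate -> render -> track -> displacement for one paced/spontaneous needle
run_single_pipeline <- function(model, noise_sigma = 0, sim_seed = 1L,
                                scene_seed = 1L, duration = 10, fps = 30) {
  sim <- simulate_trace(model, duration, fps, seed = sim_seed)
  scene <- single_needle_scene(noise_sigma, scene_seed, duration, fps)
  stack <- render_frames(sim, scene)
  tracks <- track(stack, detection_config(),
                  seeds = data.frame(x = 100, y = 80))
  traces <- to_displacement(tracks)
  list(sim = sim, scene = scene, stack = stack, tracks = tracks,
       traces = traces)
}

# ground-truth beats countable from a sampled recording: a twitch peak can
# only register as an interior maximum if it occurs at least two frames
# before the recording ends
countable_beats <- function(sim) {
  sum(sim$beats$peak_s <= sim$duration - 2 / sim$fps + 1e-9)
}

# independent closed-form pooled-variance t-test (oracle for compare_groups)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# independent permutation test on the difference of means
perm_test_oracle <- function(a, b, n_perm = 1000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  set.seed(seed)
  ge <- replicate(n_perm, {
    idx <- sample(length(pooled), length(a))
    abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
  })
  (sum(ge) + 1) / (n_perm + 1)
}
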