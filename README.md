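# needlebeat

Contraction analysis for scaffold-free engineered cardiac tissue on a
needle (Kenzan) array.

When a cardiac construct printed onto a needle array contracts, it bends
the needles; the motion of each bright needle tip, filmed through a
stereomicroscope, is a read-out of contractile behaviour. `needlebeat`
turns such recordings into quantitative beat physiology:

- **tip tracking** — normalized cross-correlation template matching with
  2-D parabolic sub-pixel refinement, one template per needle seeded on
  the reference frame (an unattended blob-detection mode exists for
  automated work);
- **displacement traces** — per-frame Euclidean distance of each tip from
  its rest position, the rest position being re-estimated from the
  lowest-motion frames so recordings may start mid-beat;
- **beat detection** — moving-average smoothing plus prominence-based peak
  picking with a refractory separation; per-beat amplitude ("top
  movement", the proxy for contractile force) is measured against the
  higher flanking trough, so incomplete relaxation under fast pacing
  shows up as reduced amplitude;
- **summaries** — beating rate in beats per 10 s (the conventional
  reporting window), per-beat amplitude statistics, and a cross-needle
  synchronisation index in [0, 1];
- **drug-response analysis** — per-timepoint amplitudes normalized to the
  pre-drug baseline (`A(t) / A(baseline)`), washout-recovery decisions,
  pooled-variance Student's *t* comparisons, and an optional
  Euler–Bernoulli cantilever conversion `F = 3 E I δ / L³`
  (`I = π d⁴ / 64`) for users who know their needles' material properties;
- **a synthetic-scene simulator** — ground-truth twitch waveforms (a
  difference-of-exponentials kernel, spontaneous beating as a jittered
  renewal process or pacing with 1:1 capture), rendered into noisy
  grayscale videos of a needle array, so every stage of the pipeline can
  be validated against known truth without any real data.

Everything tabular is a tibble, so results chain with the pipe; fitted
summaries support `tidy()` / `glance()`, and each result type has a
plot (`plot_trace()`, `plot_frame()`, `autoplot()`).

## Worked example

Simulate a 10 s recording of one needle paced at 1 Hz (10 ms pulses,
i.e. a 990 ms inter-pulse gap), render it with pixel noise, and run the
full measurement pipeline:

```r
library(needlebeat)

model <- twitch_model(protocol = pulse_schedule(1, 10))
sim   <- simulate_trace(model, duration = 10, fps = 30, seed = 1)
scene <- synthetic_scene(data.frame(x = 100, y = 80),
                         noise_sigma = 2, seed = 1)
stack <- render_frames(sim, scene)
stack
#> <nb_frame_stack> 300 frames of 320 x 240 px at 30 fps (10.00 s)

summary <- stack |>
  track(detection_config(), seeds = data.frame(x = 100, y = 80)) |>
  to_displacement() |>
  summarize_contractions(fps = 30)
summary
#> <nb_summary> 1 needle(s), 1 window(s) of 10 s
#> # A tibble: 1 × 8
#>   needle_id window t_start t_end n_beats beats_per_10s mean_amplitude_px
#>       <int>  <int>   <dbl> <dbl>   <int>         <dbl>             <dbl>
#> 1         1      1       0    10      10            10              7.03
```

The tracker recovers all ten paced beats (10 beats per 10 s — 1:1
capture), and the mean per-beat tip movement of 7.03 px sits close to
the simulated 8 px twitch amplitude (smoothing and local-trough
referencing absorb the remainder). Two-group comparisons use the classic
pooled *t*-test:

```r
compare_groups(c(6.6, 7.1, 6.9), c(4.1, 4.4, 3.8))
#>   statistic df      p_value   mean_a mean_b significant_05 significant_01
#> 1  12.23768  4 0.0002560147 6.866667    4.1           TRUE           TRUE
```

A thin CLI wraps the same functions
(`inst/cli/needlebeat simulate|track|analyze|response|run`).

## File formats

All interchange is plain text: CSV for tracks
(`needle_id, frame, time_s, x_px, y_px, confidence, missing`), traces
(`…, displacement_px`) and beats
(`needle_id, onset_s, peak_s, relax_s, amplitude_px`); JSON for nested
summaries and run manifests; YAML for scene/seed/protocol configuration;
multi-page TIFF or PNG sequences for frames. Frame indices are 0-based,
times are seconds, time = frame / fps; pixel coordinates have their
origin at the top-left with x rightward and y downward.

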