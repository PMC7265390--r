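---
title: "Measuring contraction of cardiac constructs on a needle array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contraction of cardiac constructs on a needle array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
```

```{r load}
library(needlebeat)
```

## The measurement problem

Scaffold-free cardiac constructs — tubes of fused cardiomyocyte spheroids
printed onto a grid of fine needles — bend the needles each time they
contract. A stereomicroscope camera (typically 30 frames per second) sees
the needle tips as bright blobs on a dark background. The tip deflection
amplitude per beat ("top movement") serves as the practical indicator of
contractile force, because converting deflection to newtons requires
needle material properties that are usually unavailable; the beating rate
is conventionally reported per 10-second window. `needlebeat` implements
the whole measurement chain, and — because real constructs cannot be
shipped with a package — a synthetic-scene generator whose ground truth
makes every stage falsifiable.

## The twitch model

A single contraction is modelled by a difference-of-exponentials kernel

$$k(t) \;=\; A\,\frac{e^{-t/\tau_r} - e^{-t/\tau_c}}{\max_t\left(e^{-t/\tau_r}-e^{-t/\tau_c}\right)},$$

which rises with the contraction time constant $\tau_c$ and decays with
the relaxation constant $\tau_r$, starts at 0, and peaks at exactly the
amplitude $A$ at $t^\* = \frac{\tau_c\tau_r}{\tau_r-\tau_c}\ln(\tau_r/\tau_c)$.
When $\tau_c = \tau_r = \tau$ the analytic limit $(t/\tau)e^{1-t/\tau}$ is
used. Defaults — $A = 8$ px, $\tau_c = 50$ ms, $\tau_r = 300$ ms — give a
twitch that peaks about 108 ms after onset and is visually consistent
with published needle-tip waveforms at this frame rate; the amplitude
scale in pixels is arbitrary (it depends on magnification) and fully
configurable.

```{r kernel}
m <- twitch_model()
t <- seq(0, 1.2, by = 1/300)
plot(t, twitch_kernel(t, m), type = "l", xlab = "time since onset (s)",
     ylab = "tip displacement (px)")
```

Beat timing comes in two modes:

* **Spontaneous**: a renewal process. Inter-beat intervals are Gaussian
  with mean $1/\text{rate}$ and coefficient of variation 0.05 by default
  (floored at 20% of the mean so intervals stay positive); the first
  onset is uniform in $[0, 1/\text{rate})$, which avoids phase-locking
  between the beat grid and the analysis window.
* **Paced**: one beat per delivered pulse (1:1 capture). A protocol built
  with `pulse_schedule(frequency, pulse_width)` satisfies
  `pulse_width + inter_pulse_gap = 1000 / frequency` ms exactly — 10 ms
  pulses at 1 Hz repeat every 990 ms, at 2 Hz every 490 ms. A paced
  simulation produces exactly `floor(duration * frequency)` onsets.

Overlapping twitches superpose **additively with no saturation**. This is
deliberate: at 2 Hz pacing the 300 ms relaxation tail cannot finish
inside a 500 ms period, so the baseline between beats stays elevated and
the per-beat peak-to-trough excursion shrinks — the experimentally
observed loss of "top movement" under fast pacing emerges from the model
rather than being special-cased.

One subtlety of windowed counting: a twitch whose onset falls in the
window but whose *peak* lands within the last two sampled frames cannot
register as an interior maximum of the sampled trace. Tests therefore
compare detected counts against the peaks countable in the sampled span;
`simulate_trace()` still reports every onset as ground truth.

## Scene rendering

`synthetic_scene()` + `render_frames()` draw each needle as a dim
Gaussian ridge (the shaft) capped by a bright Gaussian tip blob
($\sigma = 2$ px, default 320×240 8-bit frames), deflected from rest
along a per-needle unit direction by the trace value at that frame, plus
additive Gaussian pixel noise, quantised to 8 bits. Rendering is
deterministic given the scene seed. Two invariants are enforced at render
time: tips must stay separated by more than four times the maximum
deflection (so tracker identities cannot swap by construction), and no
tip may leave the frame.

What the generator does *not* emulate: photometric drift, defocus,
occlusion of tips by the tissue itself, non-rigid tissue texture around
the shaft, and rolling-shutter effects. Passing tests therefore
demonstrate correctness of the measurement chain under controlled
conditions, not robustness to every pathology of real microscopy video.
Real recordings should be spot-checked with `plot_frame()` overlays.

## Detection and tracking

Seeded template matching is the default tracker. Each user-supplied seed
is first refined to sub-pixel by an intensity-weighted centroid using
only pixels above the local half-peak level — the dim shaft below the tip
would otherwise drag the centre about a pixel towards the needle base —
and a $(2h+1)\times(2h+1)$ template ($h = 8$ px) is cut from the
reference frame. Every subsequent frame is searched within a Euclidean
radius (default 12 px, comfortably above the ~8 px/frame peak tip
velocity at 30 fps) of the previous accepted position by zero-normalized
cross-correlation; the integer peak is refined by a 1-D parabolic fit in
each axis, clamped to ±0.5 px. The match score is the confidence: below
`min_confidence` (default 0.5) the frame is recorded as **missing** —
never a fabricated position — and the search centre stays put. A needle
missing in more than 25% of frames carries a tracking-quality warning.
Identity maintenance is purely local; no global assignment is needed
because scene separation far exceeds deflection. By construction,
consecutive accepted positions never differ by more than the search
radius. On noiseless renders the tracker's position RMSE is about
0.06 px.

The auto-blob mode (threshold at half of peak-above-background,
connected components via `EBImage::bwlabel`, intensity-weighted
centroids, ordered left-to-right then top-to-bottom) exists for
unattended runs and serves as an independent cross-check: both modes
agree within 0.3 px on noiseless frames.

Displacement is the Euclidean distance from a rest position — hence
non-negative, with no sign convention needed for the deflection
direction. The rest position is the coordinate-wise median over the
lowest-decile-displacement frames (after a first pass anchored at frame
0), which tolerates recordings that begin mid-beat. The residual bias of
this estimator grows when the construct never fully relaxes (fast
pacing with long $\tau_r$), since even the quietest frames then sit
slightly off rest; at the default kinetics and rates up to 1 Hz it stays
well under half a pixel.

## Beat detection

The trace is smoothed with a centred moving average (0.1 s window;
reflected edges), then local maxima are screened by **topographic
prominence** with an automatic threshold of 20% of the robust
(5th–95th percentile) displacement range. Prominence, not height, is the
criterion so that a drug that halves amplitude does not change the beat
count until the signal approaches the noise floor — the behaviour
expected of a myosin inhibitor, which lowers contractile force without
touching rate. At a recording edge the prominence base falls back to the
trace's 5th percentile: displacement has a known resting floor, and a
beat peaking just before the recording ends should not be discarded only
because its relaxation was clipped. A refractory separation (default
0.2 s, admitting pacing up to ~4 Hz) is enforced greedily from the
tallest peak down. Traces whose robust range is below the noise floor
(0.05 px) yield an empty beat table, not an error.

Per-beat amplitude is the smoothed peak minus the **higher of the two
flanking troughs** (configurable to peak-above-rest). The local-trough
definition is what makes incomplete relaxation at 2 Hz read out as
reduced amplitude. Onset and relaxation times are 10% crossings between
trough and peak. Missing samples are linearly interpolated only across
gaps shorter than 3 frames; longer gaps split the trace into
independently analysed segments.

```{r beats}
sim <- simulate_trace(twitch_model(protocol = pulse_schedule(2, 10)),
                      duration = 10, fps = 30, seed = 1)
beats <- detect_beats(sim$trace, fps = 30)
nrow(beats)                 # 20 beats in 10 s at 2 Hz pacing
mean(beats$amplitude_px)    # < 8 px: incomplete relaxation
plot_trace(sim$trace, beats)
```

`beating_rate()` rescales window counts to beats per 10 s. The
synchronisation index averages, over ordered needle pairs, the fraction
of beats on one needle matched by a beat on the other within ±0.15 s; it
is 1 exactly when all beats co-occur, and a beat-free needle contributes
0 to its pairs. The 0.15 s tolerance is half the refractory separation
of the fastest admissible pacing, tight enough that independent 1.0 and
0.8 Hz needles score well below 1.

## Drug-response analysis

Per-timepoint summaries are normalized to the pre-drug baseline:
$\tilde{A}(t) = A(t)/A(\text{baseline})$, with rate carried through
unnormalized and a beat-free timepoint mapping to $\tilde{A} = 0$ (the
situation at a late cardiotoxic endpoint when contraction has ceased).
Normalization is idempotent and invariant to rescaling all raw
amplitudes — both are tested properties. Washout recovery is declared
when any post-washout timepoint returns within ±20% of baseline
(configurable; the criterion is not standardised in the field, so the
band is explicit). Hour-scale toxicity series reuse the same machinery;
`time_h` in protocol files is converted to seconds at the boundary.

Group comparisons use the classical pooled-variance Student's *t*-test
(two-sided), matching field practice, with Welch's correction behind a
flag; zero-variance degenerate inputs return p = 1 (equal means) or
p = 0 (separated means) instead of crashing. No multiple-testing
correction is applied — the analyses are single two-group comparisons.
The cantilever force conversion $F = 3EI\delta/L^3$, $I = \pi d^4/64$,
refuses to run unless Young's modulus, diameter, free length and the
pixel size are all supplied: guessing them would manufacture force
values with no physical basis, so missing properties raise a typed
error.

## Numerical and design choices

* **Coordinates and time**: origin top-left, x rightward, y downward,
  0-based frames, $t = \text{frame}/\text{fps}$; seconds everywhere.
* **Problem sizes**: validation scenes are 10 s at 30 fps (300 frames,
  320×240 px), one to four needles — large enough that rates of 0.3–2 Hz
  and pixel noise up to $\sigma = 10$ intensity units are all exercised,
  small enough for an interactive test cycle.
* **Tie-breaks**: equal-height correlation peaks take the first in
  row-major order before sub-pixel refinement; peak separation is
  enforced tallest-first.
* **Degenerate inputs**: blank frames give empty detections; flat traces
  give empty beat tables; all-missing tracks, inconsistent frame sizes,
  zero baselines and broken pacing protocols raise typed conditions.
* **Determinism**: a seed fixes traces and renders bit-exactly; onset
  draws are independent of fps, so 30 vs 60 fps renderings of one
  waveform share beat times (and beat counts, a tested invariance).

## Limitations

Compressed video containers (MP4/AVI) are not read; recordings must be
exported as multi-page TIFF or PNG sequences first. The tracker assumes
quasi-rigid bright tips on a dark background and makes no attempt at
dense optical flow; contraction/relaxation *velocity* analysis is out of
scope at 30 fps. The sync index is a co-occurrence measure, not a phase
statistic: it saturates for identical beat trains and is insensitive to
consistent sub-tolerance lags. Force estimates are Euler–Bernoulli
end-load approximations and are reported only on explicit request.
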