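---
title: "Methods: kymograph transport analysis and calcium trace metrics"
author: "kymoflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kymograph transport analysis and calcium trace metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoflux)
```

# The measurement problem

Vesicular transport of glutamate receptors along a neurite is quantified by
photobleaching a segment of the neurite — extinguishing the bright
stationary synaptic signal — and then streaming images of the dim, moving
receptor-carrying vesicles at a single confocal plane.  In a kymograph
(position along the neurite on one axis, time on the other) each directed
run appears as a sloped line; the number of such lines per recording is the
transport measure compared across conditions.  Somatic activity of the same
neurons is measured separately with a genetically encoded calcium
indicator, summarized as dF/F relative to a minimum baseline, peak
amplitude, total supra-baseline activity, and baseline level.

kymoflux implements both measurement chains and the accompanying
statistical layer (iterative modified Thompson-Tau outlier screening
followed by a two-tailed two-sample t-test), together with a synthetic-data
generator that produces image streams and calcium traces with exact ground
truth, so every stage can be validated quantitatively without access to
microscope data.

# The transport simulator

`simulate_transport_stream()` renders a field of `field_shape` pixels over
`round(duration_s / frame_interval_s)` frames (default 50 s at 100 ms/frame,
the streaming regime the package targets).  Each of `n_vesicles` vesicles
is assigned a direction (anterograde with probability `direction_mix`), a
speed drawn uniformly from `velocity_range_um_s`, and an entry time drawn
uniformly over the stream.  Anterograde vesicles enter at the cell-body end
of the neurite path and advance by `v * dt` per frame except in frames where
a Bernoulli pause (probability `pause_prob_per_frame`) holds them in place;
they leave the simulation on exiting the path.  This piecewise-constant
velocity model with pause plateaus reproduces the straight and briefly
flattened dark traces seen in real kymographs without modeling motor
exchange; direction reversals are off by default (`reversal_prob_per_frame
= 0`) because the downstream analysis counts events, not reversals.

Each vesicle is drawn as an isotropic 2D Gaussian of width
`vesicle_sigma_um` (default 0.15 µm, a diffraction-limited spot at the
default 0.1 µm pixel size) evaluated analytically at pixel centers.
Evaluating the Gaussian rather than shifting a pre-rendered stamp keeps
sub-pixel motion alias-free, which matters when velocity is later estimated
from the rendered data.  The photobleach multiplies the stationary
background by `bleach_factor` inside a corridor around the path restricted
to `bleach_window` (half-open, in micrometers of arc length); vesicles are
rendered afterwards at full amplitude, as in the experiment where cargo
entering the bleached zone is itself unbleached.  Noise is applied last:
Poisson shot noise on the noiseless image and additive Gaussian read noise,
both optional — the standard fluorescence-camera model.  Every simulation
takes a mandatory integer seed and touches no global RNG state; identical
configurations are bit-identical.

Neither the pixel size, the spot amplitude, nor the camera noise of the
original recordings is published, so the defaults (0.1 µm/px, amplitude 50
above a background of 20, read noise 2, shot noise on, velocities 1–3 µm/s
— the range typical of motor-driven vesicle transport) are declared
choices, not inferences.

What the generator does *not* emulate: optics beyond a Gaussian point
spread function, three-dimensional motion and defocus, stationary residual
puncta in the bleached zone, photobleaching decay over the stream,
motor-state switching, or cargo heterogeneity.  Passing the recovery tests
therefore shows the analysis is correct for clean bidirectional
constant-velocity transport at the stated noise levels; it does not certify
performance on recordings with strong focus drift or dense, crossing
traffic.

# Kymograph construction

`build_kymograph()` resamples the user-supplied neurite path (a polyline in
1-based pixel coordinates, first vertex nearest the cell body) at
`sampling_step_px` intervals and, for each frame in a half-open time window
`[t0, t1)`, records the **maximum** bilinearly interpolated intensity over a
band of `2 * roi_halfwidth_px + 1` samples perpendicular to the path
(default a 3-pixel band).  Maximum projection is the declared choice for
thin neurites: it is insensitive to a path traced a pixel off-center and
never dims the punctum; mean or sum projections would couple the readout to
tracing accuracy.  Positions are measured in micrometers from the cell-body
end, so anterograde motion has positive slope; time runs down the rows.
The windowing supports the common practice of analyzing a sub-interval
(e.g. 30 s of a 50 s stream) and records the window start as `t0_s`.

# Event detection

`detect_events()` operationalizes "count the sloped lines":

1. **Background.** Per kymograph column, the temporal median estimates the
   stationary background (robust to a punctum passing through any one
   column), and 1.4826 × the median absolute deviation estimates its
   spread.
2. **Candidates.** Per row, local column maxima exceeding the background by
   `detection_threshold_sd` (default 3) spreads become candidate puncta,
   refined to sub-pixel position by a three-point parabola.  Candidates
   closer than `min_candidate_separation_um` (default 1 µm) within one row
   are merged keeping the brightest: a single noisy diffraction-limited
   spot frequently presents several ragged local maxima, and leaving them
   distinct seeds duplicate tracks.
3. **Linking.** Candidates are linked frame-to-frame by nearest neighbor
   against each track's *predicted* position (last position plus an
   exponentially smoothed per-frame velocity), gated at `max_link_jump_um`
   (default 0.5 µm) per elapsed frame and tolerating `max_gap_frames`
   (default 3) missed frames.  Prediction matters: linking against the last
   seen position lets a stale noise-seeded track sitting ahead of a real
   run steal its next candidate, splitting one run into two events.  Ties
   prefer the link that preserves the track's running direction, then the
   smaller position.
4. **Filtering.** A linked track is reported as a transport event when its
   net displacement is at least `min_displacement_um` (default 2 µm), its
   duration at least `min_duration_s` (default 0.5 s), it contains at least
   `min_points` (default 5) detections, and those detections cover at least
   `min_occupancy` (default 75%) of the frames it spans.  The occupancy
   rule separates real runs (visible in nearly every frame at the signal
   levels this detector targets) from chains of isolated noise spikes
   strung together through the gap tolerance; without it, pure-noise
   kymographs occasionally produce a spurious "event" of 3–4 spikes.
   Velocity is the least-squares slope of position against time and the
   direction is its sign.

A vesicle that pauses longer than `max_gap_frames` splits into two events —
the conservative reading of "number of visible runs" — and event counts are
converted to per-minute flux by `summarize_events()`.

Two behaviors are worth knowing.  First, count-versus-threshold
monotonicity holds from about 3 spreads upward (candidate sets only shrink
as the threshold rises); *below* the noise floor the dense candidate field
disrupts linking, so lowering the threshold to 2 can paradoxically yield
fewer surviving events.  Second, at signal-to-noise around 5 the detector
recovers well-separated constant-velocity tracks essentially perfectly
(count, direction, and velocity to a few percent), but crossing or
near-parallel simultaneous tracks within the candidate-merging distance are
outside the validated regime.

# Calcium trace metrics

`compute_metrics()` computes, for a fluorescence trace sampled at
`frame_interval_s` (default regime 60 s at 250 ms, 240 samples):

* `f_min_baseline` — the minimum of the boxcar-smoothed trace (window
  `baseline_smooth_window_s`, default 1 s).  Using the raw global minimum
  would make the baseline a single-sample noise order statistic whose
  downward bias inflates every derived quantity; smoothing first gives a
  stable estimator.  A residual bias of order the smoothed noise remains:
  at 1.5% noise it inflates recovered peak amplitudes by ~4% on average,
  which is why amplitude-recovery validation is specified at low noise.
* `dff` — `(F - f_min) / f_min`.
* `total_activity` — `sum(pmax(F - f_min, 0)) / f_min`, the sum of
  supra-baseline fluorescence divided by baseline: dimensionless,
  scale-invariant, additive over disjoint transients.
* peaks — local maxima of dF/F with topographic prominence at least
  `peak_min_prominence_dff` (default 0.1) and separation at least
  `peak_min_separation_s` (default 1 s, higher peak wins);
  `mean_peak_amplitude_dff` averages dF/F at the peaks.  The peak-based
  amplitude is the primary summary; `mean_dff` (whole-trace average) is
  also reported for users who prefer a peak-free variant.

`normalize_to_control()` divides both groups by the control-group mean, the
form in which group comparisons are made.

The calcium simulator applies transients multiplicatively to a slowly
drifting baseline, `F(t) = B(t) (1 + sum_j A_j g_j(t))`, with
difference-of-exponential kernels `g(t) ∝ exp(-t/τ_d) - exp(-t/τ_r)`
rescaled to unit continuous-time maximum, so each drawn amplitude *is* the
true peak dF/F.  Defaults: baseline 100 with a ±0.5 sinusoidal drift, three
transients of amplitude 0.5–1.5 dF/F at onsets at least 5 s apart, rise
τ 0.25 s and decay τ 1.0 s (resolvable at the 4 Hz sampling of the target
regime while preserving the fast-rise/slow-decay asymmetry of fast calcium
indicators), Gaussian noise of 1.5 intensity units.  At 4 Hz the sampled
maximum can undershoot the continuous one by up to ~4% depending on onset
phase — a deliberate, documented property of simulating the real sampling
regime.

# Statistical layer

`thompson_tau_screen()` iterates the modified Thompson-Tau rule: with
sample mean, SD and
τ = t(α/2, n−2) (n−1) / (√n √(n−2+t²)), the single largest-deviation point
is removed if its deviation exceeds τ·s, and the statistics are recomputed;
screening stops when nothing exceeds the cutoff, at n = 2, or when s = 0
(ties remove the larger value first).  α defaults to 0.05 and the τ values
reproduce the published tables (1.571 at n = 5, 1.798 at n = 10, 1.885 at
n = 20).  Users should know the procedure is aggressive on small clean
samples: on clean standard-normal samples of n = 20 it removes about 11% of
points and touches ~75% of samples at least once.  It exists to strip gross
outliers (a 10-sigma contaminant is removed essentially always), not as a
general trimming rule.  The screen is applied per experimental group,
before the between-group test.

`t_test_two_tailed()` is the classical two-sided two-sample test (pooled
variance by default, matching the "Student's" naming convention; Welch by
flag), delegating to the standard R implementation with explicit conventions
for degenerate zero-variance input.  `t_test_from_summary()` reconstructs
the test from printed `(n, mean, SEM)` summaries — the form needed to check
published values — and agrees with the raw-data route to numerical
precision when given a dataset's own summaries.

# In-silico experiments and calibration

`run_transport_experiment()` chains, per simulated animal: stream →
kymograph over the full stream → event detection restricted to the bleached
segment → event count; then the per-group Tau screen and the pooled
two-tailed t-test.  `run_calcium_experiment()` does the analogous chain for
calcium metrics with control-group normalization.  All per-animal seeds
derive from the single design seed (`seed + animal index`), so a report is
reproducible from its own echoed configuration.

The calibration study in `scripts/acceptance.R` and the acceptance tests
uses a deliberately compact scene so hundreds of end-to-end replicates run
on a single CPU in minutes: 30 s streams on a 12 × 120 px field with a
10 µm fully bleached path, 10 vesicles per recording (5 in the reduced
group), spot SNR 5 with read noise only, n = 6 animals per group under the
null and n = 12 for the power scenario.  A 50% reduction in vesicle launch
rate is detected with essentially full power at n = 12 per group.

The null behavior deserves a frank statement.  The *t-test alone* is well
calibrated on this pipeline's outputs (empirical rejection ~0.05 at
α = 0.05).  The full prescribed chain — Thompson-Tau screen per group,
*then* the t-test — is anti-conservative: trimming each group's most
deviant points shrinks the within-group variance estimate and inflates
|t|.  Monte-Carlo on the statistics layer in isolation puts the screened
test's null rejection at 0.12–0.16 at α = 0.05 for n = 6–12 per group,
regardless of whether the group values are normal, Poisson or binomial;
the end-to-end imaging pipeline measures ~0.10.  This is a property of the
screen-then-test procedure itself, not of the simulation or the detector,
and it is the reason the screen should be reserved for stripping gross
contaminants rather than applied routinely to clean small samples.

# Numerical and design notes

* Pixel coordinates are 1-based (R's native matrix convention); positions
  along the path are micrometers from the cell-body vertex, and all
  time/position windows are half-open `[a, b)`.
* Frame `i` is timestamped `(i-1) * frame_interval_s`; a 30 s window of a
  50 s stream at 0.1 s/frame therefore contains exactly 300 frames.
* Bilinear interpolation weights are precomputed once per path, so
  kymograph construction is a handful of matrix operations per stream.
* Boxcar smoothing shrinks its window at the trace ends rather than
  padding; the rectangular-excursion total-activity example is exact
  because the smoothed minimum over the flat region equals the flat value.
* Degenerate inputs have defined behavior rather than errors where a
  convention exists: zero-variance t-tests (p = 1 on equal means),
  zero-spread Tau screens (no removals), empty event lists (zero flux).

# Known limitations

* The event detector assumes at most one punctum per micrometer-scale
  neighborhood per frame; dense traffic or path crossings can merge or
  split events.
* The baseline estimator does not model monotonic photobleaching of the
  indicator; a strong downward trend would bias `f_min` toward the trace
  end and inflate early-trace dF/F.
* The Tau screen's clean-sample removal rate (~11% of points at α = 0.05,
  n = 20) is a property of the published procedure itself and should be
  weighed when comparing small groups.
* Simulated noise is stationary; flickering illumination or motion
  artifacts are not modeled.
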