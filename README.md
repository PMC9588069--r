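# sptdyn

Analysis of single-molecule tracking data for nuclear proteins —
transcription factors, chromatin architecture proteins, histones — imaged
by fast 3D (multifocus) or slow 2D (HILO) single-molecule microscopy.
The package takes per-frame localizations (or pre-linked tracks) and
answers the three questions such experiments are designed around: how
fast does the factor move, how long does it stay bound, and what fraction
of it is bound.

## What it computes

**Trajectories.** Per-frame detections are linked by optimal bipartite
assignment (Hungarian) under a hard displacement gate (no link beyond
`max_displacement`; link range one frame, no gap closing), then filtered
by a minimum track length.

**Diffusion.** Per-track time-averaged mean squared displacements are
averaged over the first 9 lags and fitted to the anomalous diffusion
model

    MSD(t) = gamma * D * t^alpha,      gamma = 2 * dims

with `D` the apparent diffusion coefficient and `alpha` the anomalous
exponent (`alpha < 1` subdiffusive, `= 1` Brownian, `> 1` superdiffusive).
Individual trajectories are also fitted and split into subdiffusive and
superdiffusive sub-populations.

**Residence times.** Under bound-biased acquisition each track is one
binding event; dwell = track length × frame interval. The empirical
survival curve `S(t) = P(dwell >= t)` is fitted two ways:

* biexponential `S(t) = a e^(-k1 t) + b e^(-k2 t)` — fast non-specific
  and slow specific binding; residence time `tau = 1/k2`, corrected for
  photobleaching by the slow rate of an H2B fit at the same frame rate:
  `tau_corrected = 1/(k2 - k2_H2B)`;
* power law `S(t) = A t^(-beta)` (continuum of binding affinities),
  after dividing the curve by the bleaching survival `e^(-gamma3 t)`,
  with `gamma3` the slowest rate of a triple-exponential H2B fit.

**Binding.** A displacement gate (200 nm from the run anchor, at least
8 frames) marks bound segments within fast-acquisition tracks, and the
fraction of tracks at least 5 frames long estimates the bound fraction
per cell, compared across conditions by one-way ANOVA.

**Synthetic data.** A two-state (bound/free) trajectory simulator with
fractional Brownian motion (exact covariance), localization noise,
photobleaching and a finite axial detection slab stands in for microscope
data and provides ground truth for every recovery test.

## Worked example

Simulate a fast 3D acquisition of freely diffusing molecules
(`D = 0.3 µm²/s`, 40 ms frames, fast bleaching), link, filter, and fit:

```r
library(sptdyn)

cfg <- sim_config(n_particles = 300, n_frames = 100, D_free = 0.3,
                  k_on = 0, k_off = 1, k_bleach = 0.6, box_size = 16,
                  axial_depth = Inf, seed = 7)
truth      <- simulate_two_state(cfg)
detections <- emit_detections(truth, cfg)
tracks     <- link_detections(detections, max_displacement = 0.5,
                              frame_interval = 0.04)
tracks     <- filter_min_length(tracks, min_frames = 10)
fit_anomalous(aggregate_msd(tracks, n_lags = 9), dims = 3)
#> <diffusion_fit> MSD = gamma * D * t^alpha, gamma = 6
#>   D     = 0.2616 um^2/s  [95% CI 0.2505, 0.2733]
#>   alpha = 0.9444         [95% CI 0.9267, 0.9621]
#>   9 lags, 402 trajectories
```

The fitted `D` sits below the simulated 0.3 µm²/s because the 0.5 µm
link gate censors the largest Brownian steps — a property of gated
linking shared with the standard tracking tools, discussed in the
methods vignette.

Residence-time analysis on bound-biased 2 Hz tracks, with an H2B control
for the photobleaching correction:

```r
tf  <- simulate_bound_tracks(5000, k_off = c(0.35, 0.04), f = c(0.6, 0.4),
                             k_bleach = 0.03, frame_interval = 0.5, seed = 1)
h2b <- simulate_bound_tracks(5000, k_off = c(0.5, 0.002), f = c(0.3, 0.7),
                             k_bleach = 0.03, frame_interval = 0.5, seed = 2)
fit_tf  <- fit_biexponential(survival_curve(compute_dwell_times(tf,  min_frames = 5)))
fit_h2b <- fit_biexponential(survival_curve(compute_dwell_times(h2b, min_frames = 5)))
correct_kbias(fit_tf, fit_h2b)
#> <biexp_fit> S(t) = a e^(-k1 t) + b e^(-k2 t)
#>   a = 1.13, k1 = 0.3693 /s; b = 0.654, k2 = 0.07039 /s
#>   tau = 1/k2 = 14.21 s
#>   k_bias = 0.03187 /s -> k2_true = 0.03852 /s, tau_corrected = 25.96 s
```

The uncorrected residence time (14.2 s) under-reports the simulated
`1/k_off = 25 s`; subtracting the H2B-derived bleaching rate recovers it
(26.0 s).

A thin command-line front end mirrors the function pipeline
(`simulate | link | msd | dwell | bound | report`); see
`inst/cli/spt.R` and `?spt_cli`.

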