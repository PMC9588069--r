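---
title: "Models and methods for single-molecule tracking analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-molecule tracking analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptdyn)
```

# Scope

`sptdyn` analyses single-particle tracking (SPT) data of nuclear factors
imaged in live cells. It covers the post-detection part of the workflow:
linking per-frame localizations into trajectories, mean squared
displacement (MSD) analysis with anomalous-diffusion fitting and
sub-population splitting, dwell-time survival analysis under two competing
photobleaching-correction schemes, bound-segment detection, and
fraction-bound statistics. Spot detection from raw images, deconvolution
and microscope calibration are out of scope; the package starts from
detection tables (`frame, x_um, y_um[, z_um]`) or pre-linked track tables.

Because raw single-molecule movies are rarely shareable, the package ships
a synthetic data generator that reproduces the statistical structure the
analysis assumes. Every estimator is validated against this generator's
ground truth, against closed forms, and against brute-force oracles in the
test suite.

# The synthetic data generator

## Motion model

Each particle switches between a **bound** and a **free** state as a
continuous-time two-state Markov chain with rates `k_on` (free to bound)
and `k_off` (bound to free); the initial state is drawn from the
stationary distribution `k_on / (k_on + k_off)`. Free motion is fractional
Brownian motion (fBm) with Hurst exponent `H = alpha/2`, so that the
ensemble MSD is exactly `2 * dims * D * t^alpha`. The anomalous-diffusion
model only constrains this MSD form; fBm is the standard
stationary-increment process realizing it, and `alpha = 1` reduces to
ordinary Brownian motion. Sampling uses circulant embedding
(Davies–Harte) with a Cholesky fall-back, both exact in covariance; the
test suite cross-checks the two constructions against the analytic
fractional-Gaussian-noise autocovariance.

Bound motion is slow Brownian motion (`D_bound`, default 0.005 µm²/s)
rather than strict immobility, reflecting the ~200 nm of residual
chromatin motion that motivates the bound-detection displacement gate.
State switching is evaluated in continuous time; a frame interval that
straddles a switch moves with the state occupying the majority of the
interval (sub-frame motion blending would change nothing at the rate
regimes of interest). When an fBm episode is interrupted by a state
switch, the next episode restarts its increment process; long-range
temporal correlations do not persist across switches.

## Measurement model

Localization error is independent Gaussian noise (`loc_sigma_xy`,
`loc_sigma_z`). In 3D, detection is restricted to an axial slab
(`axial_depth`, default 3.9 µm) mimicking a multifocus microscope's
detection volume; a particle whose true z leaves the slab is lost.
Photobleaching terminates a particle permanently — no blinking, because
linking uses a one-frame link range and gap closing is out of scope. The
observed track length is therefore geometric with per-frame survival
`exp(-k_bleach * dt)`.

Randomness is organized as one L'Ecuyer-CMRG substream per particle
(`parallel::nextRNGStream`), so a fixed seed is bit-reproducible and
enlarging `n_particles` extends the particle set without reshuffling
existing particles. (A naive `set.seed(subseed)` per particle was
measurably biased in the first draw after seeding and was rejected.)

Defaults emulate a fast 3D acquisition: 40 ms frames, fast bleaching so
that most tracks last well under 40 frames, and a ~4 µm axial detection
depth. `sim_config_hilo()` instead emulates slow 2D acquisitions (100–500
ms frames) in which high free-state mobility biases detection toward bound
molecules. For dwell-time studies, `simulate_bound_tracks()` generates the
bound-biased limit directly: each track is one residence observed until
unbinding or bleaching, with mixture support (`k_off` vector plus
fractions `f`) for multi-affinity populations.

What the generator deliberately does *not* emulate: pixel-level image
formation and detection failure, anisotropic localization error
correlated with z, spot-merging at high density, drift, and re-appearance
of blinking fluorophores. Passing tests therefore demonstrate correctness
of the estimators under the stated statistical model, not robustness to
detection artefacts in raw images.

# Linking

Detections in consecutive frames are paired by optimal bipartite
assignment (Hungarian algorithm, via `clue::solve_LSAP`) under a
squared-displacement cost, with a hard gate: no link may exceed
`max_displacement` (0.5 µm for the fast 3D regime, 0.3 µm for slow 2D
acquisitions). The cost matrix is padded so that leaving a detection
unmatched costs just more than any admissible link, which makes the
minimum-cost solution maximize the number of admissible links first and
total squared displacement second. Unmatched detections open new tracks;
tracks without an admissible continuation terminate; there is no gap
closing (link range one frame). Tests verify the assignment against an
exhaustive matching oracle and verify >95% link identity on sparse
synthetic ground truth.

Two caveats are inherent to gated nearest-assignment linking and are
shared with the upstream tools this mirrors: displacements beyond the gate
are censored (biasing MSD slightly downward for fast particles), and in
dense fields the minimal-cost solution prefers shorter links than the
truth. Both effects are visible in the full-pipeline simulations at the
few-percent level in `D`.

# MSD analysis

`compute_msd()` uses the time-averaged (overlapping-window) estimator,
the field standard, which maximizes pairs on short tracks:
`MSD(n dt) = mean_i ||r(i+n) - r(i)||^2`. `aggregate_msd()` averages the
per-track curves over the first 9 lags — matching the common 10-frame
minimum track length — with dispersion reported as the SEM across tracks
and a 95% interval of 1.96 SEM.

`fit_anomalous()` fits `MSD = gamma * D * t^alpha` with `gamma = 2*dims`
held fixed, by linear least squares in log–log space, weighted by the
per-lag inverse squared relative SEM when available. The log–log linear
fit is the canonical route because it is well-posed and reproducible; a
direct nonlinear fit exists in the tests as a cross-check only.
Confidence intervals come from the linear-fit covariance, labeled as such.
Two known bias sources are documented rather than modeled: no
localization-noise offset term is included (the model has none), and the
per-track log–log slope has a small downward (Jensen-type) bias because
the log of a noisy MSD is fitted — a pure Brownian ensemble classifies
roughly 53–55% subdiffusive rather than exactly 50%.

`classify_by_alpha()` fits each trajectory individually over the same
9-lag window (so per-track and aggregate exponents are comparable), labels
`alpha <= 1` subdiffusive and `alpha > 1` superdiffusive (the tie at
exactly 1 is measure-zero and goes to subdiffusive), then refits each
subset in aggregate. Per-track fit failures are excluded from the subsets
but retained in the output table with a reason, never silently dropped.

With photobleached track ensembles the across-track mean at large lags is
noisy (a 10-frame track contributes a single displacement pair at lag 9),
so aggregate `(D, alpha)` from a few hundred tracks varies by a few
percent between runs; the reference experiments pooled thousands of
tracks per condition for this reason.

# Dwell-time analysis

Under bound-biased acquisition every detected track is treated as one
binding event; the dwell time is track length in frames times the frame
interval, with a 5-frame minimum. "Frame rate" in the dwell definition is
dimensionally a frame interval: a 5-frame minimum at 2 Hz is 2.5 s, which
matches all derived values. The empirical survival function
`S(t) = #(dwell >= t)/n` is the object all models are fitted to, by least
squares on the curve (not maximum likelihood on raw dwells, which exists
only as a test oracle).

All decay fits share three numerical policies. First, initialization is a
deterministic multi-start over rates log-spaced between `1/max(dwell)`
and `1/(2 dt)` — no RNG, so fits are reproducible. Second, decays are
parametrized with explicit negative rates and reported as positive
magnitudes. Third, time points backed by fewer than 10 surviving events
are excluded from all fits: the deep tail of an empirical survival curve
is a staircase of single-event atoms, and without the guard the slowest
rate of a multi-exponential collapses onto it.

## Biexponential route

`fit_biexponential()` fits `S(t) = a e^(-k1 t) + b e^(-k2 t)` with
`k1 > k2 > 0`, `a, b >= 0`: a fast non-specific component and a slow
specific one, whose reciprocal `tau = 1/k2` is the residence time. A
degeneracy warning is attached when `k1/k2 < 3`. Photobleaching inflates
`k2`; `correct_kbias()` subtracts the slow rate of an H2B fit acquired at
the same frame rate (`k_bias = k2_H2B`, H2B taken as stably bound), giving
`tau_corrected = 1/(k2 - k_bias)` with uncertainty propagated in
quadrature. Only `k2` is corrected; `k1` is reported raw. Mismatched
frame intervals are rejected, and `k2 <= k_bias` is an error ("dwell
indistinguishable from photobleaching") rather than a silent negative
rate.

The correction is a difference of two fitted rates, so its relative error
is amplified by `k2 / (k2 - k_bias)`; simulations at realistic rates
(specific off-rate 0.04/s, bleaching 0.03/s, 5000 dwells) recover the
true 25 s residence within ~±15%, while the uncorrected `tau`
underestimates it by roughly half. The identifiability of the fast
component also depends on the acquisition: a non-specific rate much
faster than `1/(min_frames * dt)` is erased by the dwell minimum, leaving
the biexponential effectively single-exponential.

## Power-law route

The alternative model holds that binding affinities form a continuum, so
the corrected survival follows `S(t) = A t^(-beta)` with smaller `beta`
meaning longer-lived binding. Here bleaching is corrected at the curve
level: the H2B survival is fitted with a triple exponential
(`fit_triple_exponential()`, fractions on the simplex via stick-breaking,
rates ordered, slowest rate `gamma3` = bleaching), and the factor's curve
is divided pointwise by `exp(-gamma3 t)` (`correct_survival_powerlaw()`).
Corrected values may exceed 1 and are deliberately not re-monotonized.
`fit_power_law()` then fits `log S` against `log t` by linear least
squares over the tail-guarded range.

One subtlety matters for empirical curves: survival built from dwells
with a minimum-length filter is left-truncated, and a sum-of-exponentials
constrained to total 1 at `t = 0` cannot represent a truncated mixture
without biasing its rates. `fit_triple_exponential(..., t_origin =
"first")` anchors the mixture at the first fitted time point, the exact
model for a left-truncated exponential mixture; rates keep their meaning
and fractions describe the composition at the anchor. With this anchoring
the three rates of a histone-like simulation (fast exchange, intermediate
exchange, stable-but-bleaching) are recovered and `gamma3` lands within a
few percent of the simulated bleaching rate; without it `gamma3` runs
~10% low. `beta` inherits the `gamma3` error amplified by the fitted time
range, which is the main practical fragility of the power-law route.

Censoring by the end of the movie is not modeled (the acquisition is much
longer than the residences of interest); dwells approaching the movie
length are biased and flagged as such here rather than corrected.

# Bound segments and fraction bound

`detect_bound_segments()` marks confined runs within a trajectory: a run
anchors at the first unconsumed localization and extends while
localizations stay within `r_max` (default 0.2 µm, a conservative
estimate of chromatin motion) of the anchor; runs of at least 8 frames
(320 ms at 25 Hz) become bound events, which suppresses transient
non-specific contacts. The displacement rule has two defensible readings,
both shipped: distance from the run anchor (default; order-independent
and conservative) and per-step displacement (`strategy = "per_step"`; a
slow drift can stay under the per-step gate indefinitely). Runs are
greedy and maximal, and scanning resumes after each run whether or not it
was emitted. On labeled two-state simulations at the default gates the
detector covers >95% of bound frames with ~5% false coverage of free
frames.

`fraction_bound()` computes, per cell, the proportion of tracks lasting
at least 5 frames — a proxy for the bound population under bound-biased
acquisition. For geometric track survival with per-frame survival `p` the
expected fraction is `p^4`, which the simulator reproduces.
`compare_conditions()` runs an ordinary one-way ANOVA (not Welch — the
plain method is the named one) on per-cell fractions; the degenerate
all-identical case is defined as `F = 0, p = 1`.

# Parameter defaults

| Parameter | Default | Unit | Context |
|---|---|---|---|
| `max_displacement` | 0.5 (3D fast) / 0.3 (2D slow) | µm | linking gate |
| `min_frames` (tracks) | 10 (3D fast) / 5 (2D slow) | frames | length filter |
| `n_lags` | 9 | frames | MSD window |
| `r_max` | 0.2 | µm | bound gate |
| `min_frames` (bound) | 8 | frames | bound events |
| `min_frames` (dwell) | 5 | frames | dwell minimum |
| `discard_first` | 500 | frames | dense early frames |
| `min_events` | 10 | events | survival tail guard |

# Problem sizes

The shipped tests and the reproduction script run at deliberately modest
sizes chosen to give each assertion comfortable statistical margin: 500
tracks × 100 frames for Brownian recovery, 1000 tracks per anomalous
exponent, 5000 dwells per survival fit, 10000 tracks for the histone
triple-exponential and the fraction-bound law, and 500 two-state
particles for the bound detector. These match or scale down the reference
experiments (which pooled up to ~12,800 tracks per condition) while
keeping the full suite around two minutes on one CPU.

# Known limitations

* No gap closing or blinking model; fragmented tracks are separate tracks.
* No localization-error offset in the MSD model; `D` at short lags
  absorbs it.
* Linking censors displacements beyond the gate; fast sub-populations are
  under-sampled.
* The `k_bias` subtraction assumes H2B is perfectly stable; real histone
  exchange inflates `k_bias` slightly and the corrected residence with it.
* `beta` is sensitive to `gamma3` through the exponential division; treat
  power-law exponents from short movies with caution.
* Dwells are quantized to whole frames; corrections defined in continuous
  time leave constant offsets of order `exp(gamma3 dt / 2)` that do not
  affect fitted rates.
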