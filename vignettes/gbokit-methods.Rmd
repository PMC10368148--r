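---
title: "Methods: gamma-band oscillation analysis on multielectrode arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band oscillation analysis on multielectrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gbokit)
```

`gbokit` analyzes pharmacologically evoked γ-band oscillations (GBOs)
recorded on 60-channel perforated MEAs in *ex vivo* hippocampal slices, and
ships a synthetic-recording generator so that every estimator in the chain
can be validated against a known ground truth. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic world does and does not establish.

## The measurement model

A slice lies across a 6×10 electrode grid (100 μm pitch) with CA3 under one
side and CA1 under the other; one electrode is an internal reference and is
excluded from every analysis. Raw voltage is acquired at 20 kHz in
microvolts. The analysis band is **25–59 Hz** ("slow γ"): kainate evokes
oscillations in this range in hippocampal slices, and the upper edge
excludes 60 Hz line noise.

## Preprocessing

LFPs are isolated by a low-pass IIR Butterworth filter at 100 Hz followed by
decimation to 1 kHz.

* **Filter order 4, zero-phase.** The order is not dictated by the protocol;
  order 4 applied forward–backward (effective order 8, ~48 dB/octave) is
  standard LFP practice. Zero-phase filtering is essential here because the
  downstream coherence analysis is phase-sensitive; a causal filter would
  add a frequency-dependent phase shift common to all channels (harmless for
  coherence magnitude) but would bias any zero-lag quantity and the kinetic
  timestamps. The implementation mirrors the scipy `filtfilt` contract:
  steady-state initial conditions plus odd-reflection padding scaled to the
  filter's impulse-response duration.
* **Decimation** is integer-factor sample picking after the anti-alias
  low-pass; epoch timestamps are kept in seconds so they survive resampling.
  Energy in 0–100 Hz changes by <1% through the stage (Parseval-checked).
* **Artifacts** are caller-supplied `[t0, t1)` segments per channel,
  replaced by the line joining the last clean sample before to the first
  after (the manual-cleaning convention); segments touching a record
  boundary are rejected since they have no anchor.

## Spectral estimation

Power spectra use **multitaper estimation** with discrete prolate spheroidal
(Slepian) tapers, computed from Slepian's tridiagonal eigenproblem
(RcppArmadillo); for windows longer than 2049 samples the tapers are
spline-interpolated from the 2049-point solution and renormalized, the usual
long-window shortcut. Defaults **NW = 3, K = 5, 2 s windows, 1 s step**
give ≥1.5 Hz resolution inside the 34 Hz-wide analysis band — conventional
settings for hippocampal LFP work. The one-sided density is normalized so
its integral over [0, Nyquist] equals the signal variance; **band power**
is the trapezoidal integral of the density over [25, 59] Hz, with
interpolated band edges so power is additive over adjacent sub-bands.

**Spectrograms** convolve one channel with complex Morlet wavelets
`w(t, f0) = A exp(−t²/2σ_t²) exp(2πi f0 t)` where the width parameter
`m = f0/σ_f = 25`, `σ_t = 1/(2π σ_f)`, and `A = (σ_t √π)^{−1/2}`. Samples
within 3σ_t of the record ends are flagged invalid. Note the wavelet's
amplitude response across frequency is Gaussian with standard deviation
σ_f, so the *power* ridge of a pure tone has FWHM `2√(ln 2)·σ_f`, while the
amplitude profile has FWHM `2√(2 ln 2)·σ_f`; tests assert the latter, which
is unambiguous under both conventions.

**Peak and Q factor.** `f0` is the argmax of the density in a search band,
`B` the distance between the outermost half-maximum crossings flanking the
peak (linear interpolation between bins), and `Q = f0/B`; Q > 0.5 is the
conventional rhythmicity criterion. Two choices deserve comment:

* The default *search band is 5–59 Hz*, wider than the 25–59 Hz analysis
  band, because CA3 peak frequencies fall around 21 Hz — below the analysis
  band's lower edge. The protocol text does not state the search band it
  used; both band-restricted and broadband searches are available via the
  `search_band` argument, and no intent is guessed.
* Q is computed on the *mean* PSD over the final stretch of the drug epoch
  (the last 10 min at full scale; the final half of scaled-down epochs),
  Welch-averaged over 2 s multitaper windows.

## Onset and offset kinetics

Band power during the drug epoch is fitted by nonlinear least squares to

`P(t) = c / (1 + exp(−a·t + a·b)) + d`,

with `t` in minutes: `a` the slope (1/min), `b` the midpoint (min), `c` the
amplitude and `d` the baseline (μV²). The printed form of this equation in
common write-ups of this assay is typographically ambiguous; this reading is the only
one in which `b` is a midpoint and `c` an amplitude, consistent with the
"90% of maximum" definition used downstream. Initialization follows the
standard heuristic (`d` = min, `c` = range, `b` = time of half-max,
`a = 4/(t90 − t10)`), with manual override supported as in practice; fits
that fail or return non-positive slope or amplitude are flagged and
excluded, mirroring the discard rule for channels whose sigmoid could not
be fitted.

* **GBO90** (onset latency) is the closed-form solution of the fitted curve
  reaching 90% of its **asymptote** `c + d` (not the noisy sample maximum):
  `t = b − (1/a)·ln(c/(0.9(c+d) − d) − 1)`, with an explicit undefined-
  kinetics error when the baseline already exceeds the threshold.
* **GBO90–10 / GBO10** (offset) use threshold crossings at 90% and 10% of
  the window range, with the window *minimum* as the reference level — the
  baseline for these thresholds is not defined by the protocol, and the
  minimum is the choice that makes a pure exponential decay with time
  constant τ give the closed-form interval `τ·ln 9`. Crossings are linearly
  interpolated; the last falling pass is used.
* **Fractional drug effect** is `(P_drug − P_vehicle)/P_vehicle` over the
  final stretch of each condition: negative when the drug suppresses power
  (a GABA-A antagonist wiping out interneuron-dependent γ gives values
  around −0.5), zero when nothing changes.

## Coherence

For each electrode pair, auto- and cross-spectra are averaged over tapers
and non-overlapping 2 s windows and combined as
`C_xy(f) = |S_xy(f)| / √(S_x(f) S_y(f))`, clipped to [0, 1]; band coherence
is the mean over 25–59 Hz. Some within-slice workflows describe
"zero-phase-lag" coherence; magnitude coherence of the formula above is
the default here, and the normalized real part (the zero-lag component) is
exposed as `type = "real"`, not the default. The estimator's
small-sample bias floor for independent signals is ≈ √π/(2√ν) with
ν = windows × tapers; tests and the simulator's vehicle epoch respect this
floor rather than pretending coherence is zero.

Condition windows are the **last 5 min** of the vehicle and drug epochs at
full scale, shrunk proportionally for desk-scale epochs. The **fold
change** of band coherence is defined as the drug/vehicle *ratio*, the
convention under which "no change" maps to 1. Per-pair fold
change is also the default response of the mixed models (raw drug-window
coherence is available via `response = "coh_drug"`). Both figure-level
measures — spectral coherence and Pearson correlation of band-power
envelopes — are distinct operations (`pairwise_table`,
`power_correlation_map`). Pairs involving unlabeled electrodes are
excluded. Coherence graphs connect electrodes with band coherence at or
above 0.45 (inclusive), node size proportional to band power.

## Mixed-effects models

`fit_lme()` fits, by maximum likelihood,

`Coherence ~ 1 + Regions (+ Group×Regions) + (1 | Slice) + (1 | Slice:Elec1)`

where `Regions` has reference level `within_CA3`, and `Elec1` — the first
electrode of each pair — is nested in slice. Wald t statistics use
**residual degrees of freedom** `n_obs − n_fixed` (the MATLAB `fitlme`
reporting convention this workflow descends from); no Satterthwaite
correction is applied. Fit statistics satisfy `deviance = −2·logLik` and
`AIC = deviance + 2(n_fixed + 3)` with 3 covariance parameters. Profile-
likelihood CIs for the random-effect SDs are available in
`model_report(ci_random = TRUE)`; Wald CIs are used for fixed effects.
Rank-deficient fixed designs abort with the aliased term named; a single
slice aborts because the slice intercept is inestimable. Proprietary
robust-outlier screening is out of scope; a documented median ± 5 MAD
exclusion (`exclude_outliers_mad`) is provided instead and is **off by
default**.

`simulate_lme_records()` draws pair tables from exactly this generative
model (11 slices × 12 electrodes per region by default, ≈ 276 pairs/slice
— a realistic assay size of ~3000 pair observations) for
parameter-recovery and type-I-error studies.

## The synthetic world

Each region has one latent source: Gaussian noise shaped to a Gaussian
power profile centered at the region's peak frequency with a chosen
half-maximum bandwidth — band-pass noise, not a sinusoid, so that coherence
and Q are tunable independently and periodograms show broad peaks as real
recordings do. Channel *i* in region *r* records
`w_within·s_r + w_between·s_other + noise`. Defaults:

| parameter | default | rationale |
|---|---|---|
| CA1 peak / bandwidth | 30 / 30 Hz | reported CA1 peak ≈ 30 Hz, Q ≈ 1 |
| CA3 peak / bandwidth | 21 / 28 Hz | reported CA3 peak ≈ 21 Hz, Q ≈ 0.74 |
| amplitudes (CA1/CA3) | 6 / 7 μV | drug-epoch band power ~tens of μV², CA3 > CA1 |
| `w_within` / `w_between` | 0.9 / 0.35 | within > between coherence, mid-range values |
| noise SD | 10 μV | MEA LFP amplitudes of tens of μV; keeps band coherence off the saturation ceiling |
| onset `a`, `b` | 1.2 /min, 3 min | sigmoidal onset over minutes, scaled from the ~10–15 min full protocol |
| antagonist τ | 30 s | 90→10% fall ≈ τ·ln 9 ≈ 66 s, matching ~1 min suppression |
| epochs | 120 / 600 / 120 s | desk-scale defaults; the full protocol (1 h + 1 h + 12–15 min) is available via config |

The **onset envelope applies to band power** (amplitudes scale with its
square root). This is deliberate: the kinetics module fits the *power*
sigmoid, and only under this convention does the ground truth `(a, b)`
equal the fitted parameters and `GBO90 = b + ln 9/a` hold in closed form.
Similarly the antagonist envelope decays the power with time constant τ.

The vehicle epoch is pure noise and the reference electrode emits pure
noise throughout (the protocol is silent on its treatment). Epochs are
half-open `[start, end)` in seconds. Generation is deterministic given the
seed. Note that 60 channels × 20 kHz × the full protocol needs ~8 GiB, so
desk runs pass `fs_hz = 2000` and minutes-long epochs; all tests do.

**The analytic coherence oracle.** For two channels sharing a source, the
pointwise magnitude coherence is `w²S(f)/(w²S(f) + N)`;
`expected_band_coherence()` averages this over the band. For the *peaked*
simulator sources the band-mean coherence is below the band power fraction
(Jensen gap at the band edges), so estimator validation against exact
shared fractions ρ uses `shared_noise_pair()`, whose *flat-band* sources
make the pointwise coherence constant and equal to ρ.

**What a green test establishes — and what it does not.** The simulator
emulates the statistical skeleton of the recordings: narrowband
region-specific oscillations, sigmoidal onset, coherence structure, nested
slice/electrode variance. It does *not* model volume conduction, electrode
drift, 1/f background, spikes, or distance-dependent coherence (the source
data report no distance dependence, so coherence is region-dependent
only). Green tests therefore establish correctness of the estimators and
pipeline plumbing on data with known truth, not biological fidelity; the
study's printed values come from undeposited recordings and are not
reproduction targets.

## Scenarios

`run_experiment()` orchestrates simulate → preprocess → band power →
kinetics → spectra → coherence → mixed model, writing every table plus a
JSON manifest with per-slice seeds and MD5 checksums (same seed ⇒
bit-identical outputs). Scenarios mirror the three study designs:

* **control** — intact slices; checks the within > between coherence
  ordering and CA1 > CA3 peak frequency.
* **transected** — intact vs `w_between = 0` slices with a
  `Transected × Regions` model; severing the projection leaves within-region
  coherence intact and removes the drug-induced between-region increase,
  so the `Transected × between` interaction is negative.
* **mutant** — wild-type vs a reduced-inhibition genotype, simulated as
  oscillation amplitudes × 0.6 plus CA1-specific `w_within` 0.9 → 0.55:
  band power falls everywhere, while coherence is impaired mainly within
  CA1, leaving the within-CA3 structure comparatively preserved — the
  qualitative fingerprint the scenario is meant to reproduce. These are
  sign/ordering checks only.

## Known limitations

* DPSS interpolation beyond 2049-sample windows trades exact orthogonality
  for speed (immaterial at the package's Parseval tolerance, but exact
  tapers can be forced via `max_exact`).
* Wald t with residual df is anticonservative for few slices; with ≤ 5
  slices treat fixed-effect p values as descriptive.
* The fall-time reference level (window minimum) biases `GBO90−10` short
  when the decay is truncated well above zero; use a long enough
  antagonist window.
* The simulator's coherence depends on the generation rate through the
  white-noise density (variance spread over [0, fs/2]); the analytic
  oracle accounts for this, but comparisons across `fs_hz` values should
  use the oracle, not fixed expectations.
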