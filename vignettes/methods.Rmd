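---
title: "Methods: slow-rhythm coupling between electrophysiology and fMRI connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-rhythm coupling between electrophysiology and fMRI connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowsync)
```

# The scientific problem

Inhibiting a cortical node chemogenetically (an inhibitory DREADD or a
Kir2.1 channel in mouse prefrontal cortex) suppresses most of its spiking —
and yet seed-based resting-state fMRI shows the silenced node becoming
*more* connected with its long-range targets. The mechanistic account this
package implements is oscillatory: silencing removes preferentially the
spikes that occur away from the excitable phase of ongoing slow/δ rhythms.
The residual spikes are therefore more phase-entrained, low-frequency LFP
power and interareal slow/δ coherence rise, and — because hemodynamic
coupling integrates over seconds — seed correlations in BOLD rise with
them. `slowsync` provides every quantitative step of that argument, plus
synthetic generators with known ground truth so each step is testable.

# Signal chain and its parameters

## LFP and MUA extraction

Raw extracellular records (nominal 20 kHz) are decimated to 4 kHz
(anti-alias FIR at 0.8× the target Nyquist), low-passed at 1 kHz with a
4th-order Butterworth, decimated to 2 kHz, band-passed 1–250 Hz with a
Kaiser-window FIR (transition 1 Hz, passband ripple 0.01 dB, stopband
60 dB), and resampled to 1 kHz. Every filter is applied forward and
backward, so the chain is strictly zero-phase. The MUA channel is a
4th-order Butterworth high-pass at 100 Hz followed by a 400–3000 Hz Kaiser
band-pass (transition 50 Hz, 60 dB).

Two numerical choices deserve note:

* **Zero-phase FIR via |H|².** Forward–backward FIR filtering is applied
  in the frequency domain as multiplication by |H(f)|²; this is exact, and
  it means attenuation and ripple are the squares of the one-pass design
  (120 dB / 0.02 dB) — strictly stronger than the stated one-pass numbers.
* **The 1 Hz high-pass vs the slow band.** A band-pass starting at 1 Hz
  removes the 0.1–1 Hz "slow" band that the band statistics then analyze.
  A modulation index (below) is invariant to any time-invariant
  attenuation in expectation, so on long in-vivo records this is
  self-consistent; at desk scale the −60 dB residue is below the
  estimation noise floor. `extract_lfp(raw, f_lo = 0)` therefore offers a
  low-pass-only variant, which the end-to-end harness uses for slow-band
  power and coherence.

## Spike detection

Per channel the threshold is `T = 4 · median(|x|)/0.6745`: the median
absolute value of a zero-mean Gaussian is 0.6745 σ, so `T → 4σ` on pure
noise — a robust estimate that spikes themselves barely inflate. Events
are first samples of |x| upward crossings (both polarities), and events
closer than 1 ms are merged keeping the earlier one. On unit-variance
Gaussian noise with 10⁶ samples the computed threshold is 4.00 ± 0.01.

## Spectrograms, band power, modulation index

Spectrograms use 6 s Kaiser windows (β for 60 dB sidelobes), 50 % overlap,
zero-padded onto a 0.15 Hz grid — the printed 6 s / 0.15 Hz pair is only
reachable by zero-padding, which is the reading adopted. Median smoothing
is a 2-D running median over 30 s × 1 Hz with reflected edges. Band powers
integrate over slow [0.1, 1), δ [1, 4), θ [4, 8), α [8, 12), β [12, 30),
γ [30, 70) Hz. The contrast statistic everywhere is the modulation index

$$\mathrm{MI} = \frac{A_\text{post} - A_\text{base}}{A_\text{post} + A_\text{base}} \in [-1, 1],$$

computed on linear power (the printed bounds are exact only on a
non-negative linear scale), with the value undefined when both operands
are zero.

## Coherence and phase coupling

Power coherence is Welch magnitude-squared coherence from 2 s Hann
segments with 50 % overlap; its small-sample bias is ≈ 1/K for K averaged
segments, which the tests verify by construction. The γ-envelope analysis
integrates spectrogram power over 30–70 Hz from 2 s windows with 75 %
overlap ("0.75 percent overlap" is read as the fraction 0.75 — 0.75 %
would contradict the stated 0.5 s output step), and envelope coherence is
averaged over 0.02–0.5 Hz. The 1/f correction (least-squares line in
log-power vs log-frequency, subtracted in log space) is applied to the
envelope *spectrum* for peak localization; it cancels identically in
magnitude-squared coherence, so the coherence path uses raw envelopes.

Instantaneous phase is the angle of the analytic signal after a zero-phase
3rd-order Butterworth band-pass, with phase 0 at oscillation peaks and π
at troughs. Two numerical safeguards:

* narrow bands at extreme normalized frequencies make the polynomial
  Butterworth degenerate (poles clustered at z ≈ 1), so the signal is
  decimated until the upper band edge exceeds ≈ fs/50, filtered at the
  reduced rate, and the unwrapped phase interpolated back to the input
  grid;
* zero-phase IIR padding uses symmetric (even) reflection. The common
  odd-reflection default carries a DC offset of 2x₁ in the pads, which
  rings through narrow low-frequency band-passes and corrupts short
  records (we verified scipy's `filtfilt` exhibits the same transients);
  even reflection trades this for a slope discontinuity whose transient
  is negligible in the bands used here.

The LFP–LFP phase-locking value is
$\mathrm{PLV} = N^{-1}\left|\sum_j e^{i(\theta_1(t_j)-\theta_2(t_j))}\right|$,
the resultant length of the phase-difference distribution; the spike PLV
is 1 minus the circular variance of spike-triggered phases (numerically
the same resultant). Significance is conjunctive: the observed PLV must
exceed the 95th percentile of surrogates built by circularly time-shifting
one raw signal (≥ 1 s, before filtering; spectrum-preserving and
conservative) *and* exceed 0.1. A full-permutation surrogate is available
as an option; the under-specified "shuffling in time" is resolved in favor
of circular shifts, with both implemented.

## Spike-locking simulation

Two 10 s scenarios of spikes locked to a 1 Hz cosine: "inhibited" = 100
spikes from von Mises(µ = π, κ = 20); "sham" = those plus 100 spikes from
von Mises(κ = 0.5). The generator draws phases and places each spike in a
uniformly chosen cycle (pooled-over-epoch; the per-cycle alternative is
not implemented, and the choice is recorded here as the open question's
resolution). Trains are binarized at 1 ms, smoothed with a Gaussian kernel
whose *width is its SD* (100 ms default), and the PSD is a DPSS multitaper
estimate (time–bandwidth 4, 7 tapers; unprinted settings, overridable).

One substantive resolution: the mean phase of the diffuse population is
not printed, but it is described as "asynchronous, off-preferred-phase"
firing. With the diffuse mean *at* the preferred phase, its weak locking
(resultant A₁(0.5) ≈ 0.24 per spike) adds coherently and the mixed
scenario's 1 Hz line exceeds the locked-only scenario's — making the
stated conclusion (inhibition raises relative slow power) unreproducible.
The diffuse mean therefore defaults to the antiphase; `sim_spec()` exposes
`diffuse_phase` for sensitivity analyses.

## fMRI branch

Preprocessing drops the first 120 volumes, regresses 6 motion traces plus
the mean ventricular signal (optionally the global mean) from every voxel,
then band-passes 0.01–0.1 Hz (0.01–0.25 Hz for the
medetomidine–isoflurane variant) with a zero-phase frequency-domain
filter — at TR = 1 s and ≈ 2000 volumes a realizable FIR with the required
transition would be longer than the record. Seed maps are Pearson
correlations with the seed-mean time course; group contrasts are pooled
two-sample t tests on Fisher-z-transformed r (the transform is standard
for correlation comparisons; whether the original analysis used raw r is
unstated), thresholded at |t| > 2, with an optional label-permutation
maximum-cluster-size correction standing in for the external FWE cluster
tool. K-means partitions voxel connectivity profiles with a fixed seed and
20 restarts.

# The synthetic world

The generators state a world; they are not tuned to make tests pass:

* **LFPs.** `gen_coupled_lfp()` builds sums of shared sinusoids with
  per-channel phase offsets plus white noise — sufficient for phase-lag
  and tone-coherence ground truth. Because a shared pure tone has
  coherence 1 at any amplitude, the end-to-end harness instead uses
  `gen_band_coupled_lfp()`: band-limited Gaussian components shared across
  channels (constant phase rotation on the analytic signal) plus
  independent in-band noise, so band coherence sits strictly between 0
  and 1 and responds to amplitude changes.
* **Raw records.** LFPs are linearly resampled to the raw rate, spikes are
  inserted as a Gaussian-enveloped biphasic template (~1 ms, carrier
  ≈ 1.3 kHz — a hard-edged template rings at the 400 Hz band edge and
  produces spurious crossings), and white noise is added. The harness
  band-limits the LFP-level noise below 80 Hz because white noise at the
  LFP rate folds interpolation images into the MUA detection band.
* **BOLD.** Regional latent signals are 0.005–0.08 Hz Gaussian processes
  given a target correlation matrix by a Cholesky factor (the harness
  builds it from one-factor loadings, which is positive semi-definite by
  construction), optionally convolved with a canonical double-gamma
  kernel (identical across regions, so correlations are preserved; off by
  setting `hrf = FALSE`), plus linear drift, motion leakage, white noise,
  and an independent ventricular nuisance signal.

What a green end-to-end test establishes: the pipeline's estimators
recover the stated generating parameters and reproduce the qualitative
inhibition signature. What it does not establish: anything about real
tissue — there is no biophysics here, no vascular model, no empirical
hemodynamic response estimation, and the in-vivo effect magnitudes
(including the reported δ-band R² against connectivity) are not
reproducible from synthetic data.

# Desk-scale choices

The in-vivo protocol uses 15-min baselines, 35-min active windows and
n = 4–5 subjects per group. The end-to-end harness defaults to 90 s
epochs, a 10 s transition, 3 subjects per group, and an 8 kHz raw rate
(the floor imposed by the 3 kHz MUA edge). These were set by estimator
variance, not effect size: a 6 s spectrogram window cannot resolve power
below ≈ 0.3 Hz, so the harness keeps its shared slow component at
0.35–0.9 Hz and uses 6 s Welch segments for slow-band coherence — at the
paper-scale epoch lengths neither restriction would be needed.

# Known limitations

* The slow band below ≈ 0.3 Hz is effectively unmeasurable with 6 s
  analysis windows; slow-band statistics at desk scale reflect the upper
  part of the band.
* Surrogate-based PLV significance assumes approximately stationary
  signals over the analysis window.
* `independence_lag()` reads the "95th percentile" criterion as the white-
  noise 95 % confidence bound (±1.96/√n); the alternative reading (the
  95th percentile of the autocorrelation's own values) is implemented as
  `criterion = "percentile"`.
* The Benjamini–Hochberg step never decreases a p value and is monotone in
  rank, but the smallest q generally exceeds the smallest p; no claim of
  equality is made.
* NIfTI-1 support covers uncompressed single-file little-endian
  float32/float64/int16 — the subset this package writes.
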