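---
title: "Source-localized EEG alpha / BOLD coupling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-localized EEG alpha / BOLD coupling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Simultaneous EEG-fMRI promises millisecond temporal resolution on top of
millimetre spatial resolution, but the two signals live on different
grids and the MR environment wrecks the EEG: every gradient switch
injects millivolt-scale periodic artifact, and each heartbeat moves the
electrodes in the static field (the ballistocardiogram, BCG). The
analysis this package implements couples *induced oscillatory power at
estimated cortical sources* with the BOLD time course, trial by trial:
instead of picking one electrode (which mixes sources) or one ICA
component (which requires knowing the topography a priori), a
source-localized patch of interest (POI) defines a weighted combination
of all channels, and its single-trial alpha power, convolved with the
hemodynamic response, predicts the BOLD signal in a GLM. The benchmark
physiology is the robust *inverse* relation between posterior alpha
(8-13 Hz) power and occipital BOLD.

Because no recording accompanies the design, a synthetic multimodal
generator (`simulate_session()`) produces every input with known ground
truth, and the whole chain is tested against it.

# The processing model, stage by stage

## In-scanner EEG cleaning (`clean_session()`)

Order is fixed and enforced: gradient template subtraction, 70 Hz
zero-phase IIR lowpass (order-8 Butterworth, i.e. 48 dB/octave, applied
forward-backward), downsample to 500 Hz, R-peak detection and BCG
template subtraction, downsample to 250 Hz, +/-300 uV amplitude
rejection, 63-component ICA cleanup, then average reference with AFz and
FCz reconstructed by spherical-spline interpolation (65 channels out).
Enforcement is evidence-based: an operation refuses to run while the
markers prove an earlier artifact is still present (e.g. BCG subtraction
on data whose volume-sync markers show the gradient stage never ran).

* **Gradient artifact.** Exactly TR-periodic given a synchronized clock;
  each volume epoch is corrected by the sliding average of the
  surrounding 21 epochs (odd count centres the template). The residual
  cost is a smoothed copy of the EEG at 1/21 of its amplitude.
* **BCG.** R-peaks are detected by normalized cross-correlation against
  a template built from high-confidence peaks; epochs from 210 ms after
  each R-peak (-100..+600 ms around the lagged peak) are corrected by a
  21-epoch sliding average. Truncated epochs at the recording edges are
  corrected with the nearest full template rather than skipped -- leaving
  even one beat uncorrected dominates the residual on short records.
* **Amplitude rejection** marks (never deletes) samples beyond the
  threshold, padded by 200 ms, and reports per-channel fractions; this
  fraction is the data-quality benchmark (< 10% per channel on default
  synthetic sessions).
* **ICA** is a deterministic symmetric FastICA with log-cosh contrast --
  the practical equivalent of extended infomax for super-Gaussian
  artifact sources -- fitted on every second non-rejected sample.
  Components are flagged automatically (the design replaces visual
  identification): absolute correlation with the frontopolar blink
  reference or the ECG channel above 0.7, or a frontally focal
  topography (top-2 mixing-weight share > 0.8) with moderate blink
  correlation. Thresholds are arguments and are logged in the returned
  decomposition.

## Sensor- and source-level induced power

The Morlet convention is `c = f0 / sigma_f`: at `f0 = 10.5` Hz and
`c = 4.2` the spectral s.d. is 2.5 Hz, matching an alpha band quoted as
10.5 +/- 2.5 Hz. The wavelet is amplitude-normalized so a unit sinusoid
at `f0` yields plateau power 1. "Induced" means power is computed per
trial *before* averaging; the evoked mean is not subtracted first (a
documented choice -- the induced/evoked distinction only matters for
phase-locked components, and the generator's alpha is not phase-locked).
Under one common definition of wavelet "length" (2 sigma_t) our setting
gives 127 ms; we log the effective support rather than matching any
particular printed length. Samples within one wavelet half-support of a
segment edge are invalidated (NA) and excluded from statistics.

Segments span -2000..+1000 ms around stimulus onset; trials are excluded
(with logged reasons) for missing responses, errors on non-incongruent
trials, presentation uncertainty above 10 ms, segment amplitudes beyond
+/-125 uV, or proximity to the recording edge. Responded incongruent
trials are kept irrespective of correctness, harmonizing the EEG
exclusion rule with the GLM inclusion rule. Baseline correction
subtracts the mean power in -1500..-500 ms (percent change available).

Source-level band power uses a short-time FFT: 500 ms Hann-tapered
windows shifted by 100 ms (80% overlap), band power = mean one-sided
periodogram power in 8-13 Hz, baseline-corrected against all windows
fully contained in -2000..0 ms. Post-stimulus statistics average windows
whose *centres* fall in the analysis window (200-400 ms by default).

## Forward model and inverse

The head is four concentric shells (brain/CSF/skull/scalp) with radius
fractions 0.87/0.92/0.96/1.00 of a 92 mm scalp sphere and conductivities
0.33/1.0/0.0042/0.33 S/m -- standard values; the model class, not the
parameters, is the methodological commitment. Lead fields are the
analytic per-degree Legendre solution: within each shell the potential
is `A r^n + B r^-(n+1)` times the angular term, the seven shell
coefficients per degree follow from potential/current continuity and the
insulating outer boundary, and radii are normalized by the scalp radius
so powers up to the truncation degree (N = 60; relative error < 1e-6 for
sources within 0.9 of the brain radius) stay finite. With equal
conductivities the solution collapses onto the homogeneous-sphere
closed form -- the test oracle. A central dipole is *not* silent in EEG
(that is an MEG property); it produces a pure first-degree cosine
pattern, and the tests assert exactly that.

The source space is a Fibonacci lattice per hemisphere (up to 2500
vertices each) on a sphere at 0.85 of the brain radius, with radial
("cortex-normal") orientations -- a stand-in for a decimated cortical
mesh; geodesic caps around the occipital pole and the medial prefrontal
direction play the role of anatomical patches. Electrodes are
co-registered by rigid fiducial alignment (Kabsch) plus radial
projection onto the scalp shell.

The inverse is the weighted minimum norm with noise normalization:
`M = R L' (L R L' + lambda^2 C)^-1`, `lambda^2 = trace(L R L') /
(trace(C) snr^2)` with SNR 5 by default, `R` a depth weighting
`||L_i||^(-2 gamma)` with `gamma = 0.5`, and each source estimate
divided by its predicted noise s.d. `sqrt((M C M')_ii)`. The noise
covariance is the 65 x 65 sample covariance of the pre-stimulus
(-2000..0 ms) samples with light diagonal loading. The regularization
share of the Gram-matrix trace is reported as a diagnostic
(`trace_fraction`); a published value of lambda tied to someone else's
empirical covariance is not reproducible from text and is not targeted.
Localization is insensitive to SNR in [1, 10], which the tests assert as
argmax stability.

Source maps are across-trial t tests per vertex (one-sample against
baseline for audiovisual trials; Welch two-sample for CON vs INC) --
the map statistic is not specified beyond "p < 0.05" in the source
material, so the package documents its choice.

## EEG-informed fMRI

POIs are contiguous supra-threshold vertex clusters (neighbours within
1.6 typical edge lengths), largest first, weights proportional to |t|.
Single-trial POI alpha projects each sensor segment through the
noise-normalized kernel restricted to the POI, computes baseline-
corrected STFFT alpha power, and averages with the POI weights. The
regressor is a stick function at stimulus onsets scaled by trial alpha
(zero outside events), convolved with a canonical double-gamma HRF
(peak 6 s, undershoot 16 s, ratio 1/6, unit peak) on a 10 ms grid and
decimated to the TR grid -- convolving at event resolution avoids onset
quantization bias. BOLD preprocessing discards two volumes, smooths at
4 mm FWHM (kernel renormalized at the edges so constants are preserved
exactly), and removes a linear trend plus discrete-cosine drift slower
than 128 s. The GLM is voxelwise OLS; both t and the equivalent partial
correlation r are emitted, since "correlation map" is ambiguous between
them. Cluster extent is calibrated by Monte-Carlo simulation of
(optionally smoothed, re-standardized) Gaussian noise volumes,
two-sided voxel threshold, 95th percentile of the max-cluster null plus
one; connectivity is 6-neighbour and configurable.

# What the generator emulates -- and what it does not

The default `simulate_session()` is desk-scale: 4 blocks / 48 trials
instead of 32 blocks / 384, simulated directly at 500 Hz instead of
5000 Hz (the 5000-to-500 Hz chain is exercised by unit tests); pass
`paradigm = paradigm_spec()` for the full session. Everything else is
the stated world regardless of scale: 12 trials per block, 19-21 s
jittered pauses, 1-1.2 s stimuli with 1 s decision and 1 s response
phases, emotion-balanced blocks with randomly mixed CON/INC audiovisual
trials.

Stated or field-standard generator choices (chosen once, not revisited):

* **Occipital suppression**: the alpha envelope drops by
  `suppression_depth` (default 0.5, i.e. post-stimulus power 25% of
  baseline) in 200-400 ms after every stimulus, with 10% multiplicative
  trial-to-trial jitter; congruent audiovisual trials add a frontal
  envelope gain (default 0.5). The per-trial realized power change is
  the coupling ground truth.
* **Alpha coherence**: the oscillator's instantaneous frequency wanders
  around 10.5 Hz (AR(1), s.d. 0.5 Hz, ~0.5 s correlation time). This is
  physiological -- real alpha has coherence times well under a second --
  and it matters technically: a phase-rigid 10.5 Hz sinusoid is exactly
  TR-periodic (21 cycles per 2 s volume), so gradient template
  subtraction would remove the rhythm itself, a degeneracy of the toy
  signal rather than of the method.
* **Artifacts**: gradient bursts are 34 slice-locked sawtooths per 2 s
  TR at 1500 uV scale (pre-cleaning sensor SNR << 1); BCG is a fixed
  per-channel waveform 210 ms after each R-peak at ~3x EEG RMS with 5%
  beat-amplitude jitter; blinks arrive at 12/min with ~250 uV frontal
  peaks (25% amplitude jitter), so a realistic minority crosses the
  +/-300 uV rejection threshold.
* **Behavior**: per-condition accuracies 70.8 / 93.8 / 92.9% (auditory /
  visual / congruent), incongruent decisions split 0.500 / 0.278 / 0.222
  face / voice / neither (the printed percentages sum to 102%, so the
  normalized proportions are used and the printed ones are not
  targeted), 2% omissions.
* **BOLD**: 20 x 20 x 10 grid at 3 mm, TR 2 s; a posterior cuboid of
  voxels follows `k = -2` times the HRF-convolved ground-truth trial
  alpha, all voxels carry Gaussian noise (s.d. 1) and sub-0.01 Hz drift.

Not emulated: real anatomy and Talairach registration (spherical
geometry substitutes), slice-timing and motion (the synthetic BOLD is
motion-free), MR physics, realistic stimulus material, and
between-subject variability. A green test therefore establishes that the
*pipeline* recovers known effects through realistic artifact levels --
not that it would reproduce any particular participant's maps.

# Numerical choices and degenerate inputs

* Butterworth filters run as second-order sections (stable at order 8
  and low relative cutoffs) with odd-symmetric edge padding for the
  zero-phase pass.
* Integer-factor resampling is polyphase (anti-alias filtfilt +
  decimation); non-integer ratios use FFT resampling. The
  repeated-equals-direct identity holds to 1e-6 on the FFT path and to
  filter tolerance on the polyphase path.
* Marker onsets rescale with round-half-even; ties cannot bias onsets.
* Flat ECG warns and returns zero peaks; zero-amplitude artifacts pass
  through their removers with only averaging noise; an amplitude
  threshold of 0 rejects everything with a warning; rank-deficient data
  make ICA fail with advice rather than proceed.
* The spline system carries a 1e-5 ridge; the lead-field series is
  truncated at degree 60; the inverse Gram matrix is always regularized
  through `lambda^2 > 0` -- a singular system is an error instructing
  the user, not a silent pseudo-inverse.

# Known limitations

Spherical geometry everywhere (head model, cortex, montage) means no
claim about anatomical accuracy transfers to real heads; the automatic
ICA rules are tuned to the simulated artifact repertoire and would need
recalibration for real EOG/EMG; the Monte-Carlo cluster threshold
assumes stationary Gaussian smoothness; and the desk-scale defaults
trade statistical power for runtime, so effect-size estimates from the
default session are noisy by design.
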