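---
title: "Methods: frequency-tagged and evoked OPM-MEG analysis in opmpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged and evoked OPM-MEG analysis in opmpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(opmpipe)
```

## What the package computes

`opmpipe` implements an analysis chain for wearable optically pumped
magnetometer (OPM) magnetoencephalography of auditory responses in newborns:

1. **Evoked responses** to tones presented with a 500–600 ms random onset
   asynchrony: epochs from −70 to 500 ms, baseline-corrected over the 70 ms
   prestimulus interval, averaged per participant and across participants,
   summarized by the across-channel root-mean-square (RMS) peak latency, the
   peak amplitude, and the amplitude/baseline-SD ratio.
2. **Frequency-tagged oddball responses** to 3 Hz tone trains in which every
   fourth tone deviates (0.75 Hz): 20 s oddball-locked epochs, epoch-averaged
   complex Fourier coefficients, the power spectrum, and the flanking-bin SNR
   statistic
   $$\mathrm{SNR}(f) \;=\; \frac{P(f)}{\overline{P}\big(\,0.1 \le |g-f| \le 0.4\ \mathrm{Hz}\,\big)},$$
   evaluated on the 0.05 Hz grid set by the 20 s epoch (7 flanking bins per
   side, endpoints inclusive).
3. **Inference** by step-down maximum statistics with two surrogate
   constructions: per-epoch (or per-participant) sign flips for time-domain
   evoked maps, and per-epoch per-bin Fourier phase randomization for the
   SNR maps, both applied identically across channels to preserve the spatial
   covariance under the null.
4. **Source analysis** with an analytic homogeneous-sphere dipole forward
   model and a noise-normalized minimum-norm inverse; for the oddball
   paradigm, sources are reconstructed per participant from the averaged
   Fourier coefficients (group-averaged SNR is not linear in the field) and
   the source-level SNRs are then group-averaged.

Every stage runs on synthetic recordings from the package's own generator, so
each claim about the chain can be checked against known ground truth.

## The synthetic recordings

`sim_config()` fixes the study conditions: 5-minute sequences at 1200 Hz on a
~27-sensor array (mean of the emulated setup; 19–30 housings, ~20 triaxial,
placed with a Fibonacci lattice on the upper three quarters of a 65 mm sphere
with a 4 mm standoff, none in the occipital patch, triaxial housings
preferentially lateral). Signals are generated through the same spherical
forward physics used by the inverse:

* **Evoked response**: a difference-of-gamma biphasic bump per tone, peak at
  260 ms (configurable), injected at bilateral temporal dipoles
  (±45 mm laterally, anterior-oriented moments), scaled so the per-event
  average peaks at 2 pT on the best channel. The waveform is time-shifted so
  its analytic maximum sits exactly at the configured latency; tests rely on
  that oracle.
* **Steady-state response**: sinusoidal lines at 3 Hz (1.5 pT) plus
  oddball-locked lines at 0.75 and 1.5 Hz (0.6 and 0.36 pT). The cycle starts
  on an oddball so 20 s epochs tile the recording. No 2.25 Hz neural line is
  simulated: that frequency sits inside the infant heart-rate band, where
  residual cardiac artifact dominates real recordings.
* **Noise and artifacts**: flat sensor noise (25 fT/√Hz); per-channel 1/f
  noise (25 fT/√Hz at 1 Hz) and linear drift; rank-1 heartbeat artifacts
  (pseudo-ECG with 3% cycle jitter; infant rate drawn from 2.2–2.5 Hz at
  3 pT, parent from 1.0–1.5 Hz at 1 pT); sparse movement bursts (2/min,
  20 pT, 0.5–2 s); and a rank-3 **homogeneous ambient-field** component
  (a slowly fluctuating field vector projected on each channel's orientation,
  20 pT rms per axis). The ambient term is what makes the
  principal-component projection stage meaningful: it is the dominant,
  spatially low-rank interference of wearable arrays, and without it the
  projection's leading components would be the neural pattern itself.

What the generator does **not** emulate: non-stationary heart morphology,
sensor calibration errors and gain drift, cross-axis crosstalk, real room
interference spectra, head movement relative to the array, and anatomical
conductor geometry. Passing tests therefore demonstrate the correctness and
calibration of the *analysis machinery* under controlled conditions, not
performance on real recordings.

All randomness flows from one seed; per-component sub-seeds are derived
deterministically, so identical configurations reproduce recordings
bit-for-bit.

## Preprocessing decisions

* **Artifact detection**: the robust z-score rule (smoothed 1 s amplitude,
  median/MAD with the 1.4826 consistency constant, threshold 5, per channel)
  replaces interactive marking. The initial pass runs on a 1–40 Hz
  band-passed copy: on raw data the 1/f ambient field dominates the smoothed
  amplitude and over-flags. Detected windows are extended by 1.5 s on both
  sides and merged; epochs intersecting them are rejected.
* **Filtering** is FFT-domain and exactly zero-phase (latencies are headline
  outputs): unit passband, raised-cosine transitions (low edge rolls on
  between `low/2` and `low`, high edge off between `high` and `1.1·high`),
  reflect padding of 10 s. A 4th-order forward–backward Butterworth was
  rejected after measurement: at 0.2 Hz/1200 Hz the transfer-function form
  diverges numerically, and no stable realization available here reaches the
  required 40 dB at 50 Hz for a 40 Hz band edge.
* **Notch**: narrow lines (detected automatically as bins exceeding a
  running-median baseline tenfold within 13–40 Hz) are removed by
  segment-wise least-squares sinusoid regression (10 s segments) — exact
  removal of the coherent line, zero phase distortion, neighbours untouched.
* **Heartbeat removal**: symmetric FastICA (tanh contrast) fitted on the
  artifact-free, 1–40 Hz data (decimated to ≤ 12 000 samples for the fit); a
  component is removed when its flanking-bin spectral SNR within a
  heart-rate range exceeds 7.5. In the oddball path the screening skips bins
  within 0.1 Hz of stimulation-locked frequencies, because the tagged
  1.5 Hz harmonic lies inside the parent heart-rate prior and would
  otherwise be flagged. Heart-rate ranges for the second screening pass are
  the dominant 0.8–3.5 Hz peaks of flagged components ± 0.15 Hz (the
  half-width that reproduces a 2.2–2.5 Hz span from a 2.35 Hz rate). With
  mostly-Gaussian data the rotation within the ICA noise subspace cannot
  reach tolerance; after two seeded restarts the final iterate is used with
  a warning (hard error only for non-finite results) — the non-Gaussian
  artifact directions converge regardless.
* **PC projection**: the top 3 spatial principal components of the
  artifact-free data are projected out of all samples (`I − UU'`), removing
  the rank-3 ambient interference exactly.

## Inference decisions

* Statistic maps: `|mean|` per channel × time for evoked data; SNR per
  channel at each frequency of interest for tagging, tested per frequency.
* The step-down loop declares an element significant when its empirical
  p-value `(1 + #{surrogate max ≥ observed}) / (1 + n_surrogates)` is at
  most α, masks it, and re-tests the remainder against the null of the
  maximum over the unmasked set, stopping when nothing is added. The
  `(1+k)/(1+n)` convention keeps p strictly positive (floor 1/10001 at the
  default 10 000 surrogates) and makes "significant ⇒ p ≤ α" an exact
  invariant; the reported per-iteration threshold is the empirical
  `1 − α` quantile (R's default type-7).
* Sign flips are drawn once per unit and shared across channels; with n
  units the attainable p floor is `2/2^n`, so group-level significance needs
  at least 7 participants at α = 0.05.
* Phase randomization draws one uniform phase per epoch **and per frequency
  bin**, shared across channels (a per-epoch-only variant is available via
  `granularity = "epoch"`). Per-bin draws also randomize within-epoch phase
  structure; magnitude spectra of every epoch and channel are preserved
  exactly, and flank bins shared by two tested frequencies reuse the same
  draws through per-bin seeding.
* Pairwise comparisons are two-tailed t-tests gated by Shapiro–Wilk at 0.05
  (on paired differences, or each sample); otherwise Wilcoxon signed-rank /
  rank-sum with the normal approximation. Degenerate all-zero paired
  differences return p = 1 by convention.

## Source analysis decisions

* The forward model is the analytic current-dipole solution in a homogeneous
  spherical conductor fitted to the array (radially oriented moments are
  externally silent; the implementation is cross-checked in the tests
  against an independently computed fixture). MEG forward fields are
  comparatively insensitive to conductor detail, which is what makes the
  sphere an adequate desk-scale stand-in for anatomical models.
* The inverse is `W = L'(LL' + λ²·g·C)⁻¹` with identity source covariance,
  `g = tr(LL')/tr(C)` and λ² = 1/9 (amplitude SNR 3). Depth-bias correction
  defaults to sLORETA-style standardization by the 3×3 resolution blocks
  `(WL)_jj`, pseudo-inverted so the silent radial orientation does not
  amplify noise: this form has zero localization error for a noiseless point
  source, which the recovery tests exercise; dSPM-style noise-SD division
  (which showed a ~2 cm peak bias in the same noiseless benchmark) and raw
  minimum-norm output remain available via `method`.
* The source grid is a 7.5 mm regular lattice within 85% of the sphere
  radius; auditory ROIs are lateral wedges around the ±y axis (half-angle
  ~56°, eccentricity ≥ 45%), and hemispheric summaries take the ROI argmax.

## Problem sizes

Defaults mirror the study conditions (13 participants, 5 min at 1200 Hz,
10 000 surrogates). The test-suite and the acceptance script run the same
code on reduced sizes chosen as the package's own verification conditions:
5 participants × 120 s at 600 Hz for the end-to-end pipelines, 400 runs ×
500 surrogates for the family-wise-error calibration, 50 seeded runs for
recovery and detection rates, and 10–12 epochs where exhaustive sign-flip
enumeration serves as the oracle.

## Known limitations

* The template-layout matching assumes equal per-axis channel counts across
  participants (true of the generator); heterogeneous real caps would need
  sub-matching or interpolation.
* The SNR statistic inherits the 0.05 Hz grid of 20 s epochs; recordings
  shorter than ~20 s of artifact-free data cannot be screened or analysed.
* Segment-wise notch regression assumes lines are narrow and roughly
  stationary within 10 s.
* The spherical conductor ignores anatomy; localization claims are relative
  to the model's own geometry.
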