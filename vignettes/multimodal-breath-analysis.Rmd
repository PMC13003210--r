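---
title: "Methods: multimodal breath analysis from impedance pneumography and lung sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal breath analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `mmbreath`. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The measurement model

Impedance pneumography (IP) exploits the fact that transthoracic
electrical impedance rises as the lungs fill with air. A wearable
sampling multifrequency bioimpedance at 16 Hz therefore carries a
quasi-periodic respiratory oscillation; the channel at the highest
excitation frequency drives the analysis. Simultaneously recorded
chest-wall audio contains breath sounds whose intensity and spectrum
depend on the breathing phase: normal lung sounds are
inspiration-dominant and spectrally concentrated at low frequencies,
while airway narrowing adds tonal (wheeze) energy above roughly 300 Hz.

The package's central idea is *phase contextualization*: the IP signal
supplies, for every breath, the inspiration onset, the
inspiration-to-expiration transition and the breath end; those
timestamps index the audio so that spectral features can be computed
per phase. A breath's feature vector has 13 entries: RR, Ti, Te,
Te:Ti, Ti/IBI from the IP branch, and the four subband spectral
integrated intensities (SIs) for each of the two phases from the audio
branch.

## Fiducials and breath timing

An interbreath interval runs trough-to-trough in the band-passed IP
signal, with the peak as the inspiration-to-expiration transition. This
convention makes Ti + Te = IBI exact by construction; the literature
rarely states its fiducial convention, and this is the one under which
the timing identities are identities rather than approximations.

Detection operates on 32-s windows overlapping by 2 s, with local
maxima at least 0.67 s apart (so the detectable rate is bounded by
60/0.67 = 89.55 breaths/min). Two implementation details go beyond the
usual textbook recipe and deserve justification:

- **Peak-height floor.** Within each window, candidate peaks below 10%
  of the 95th percentile of |signal| are discarded. The zero-phase FIR
  band-pass leaves passband ripple on breath slopes whose local maxima
  would otherwise be promoted to (tiny, spurious) breaths.
- **Fiducial refinement.** The respiratory band-pass (0.1–1 Hz
  nominal) keeps only a handful of harmonics of the breathing
  frequency; on asymmetric breaths (Ti ≠ Te) this harmonic truncation
  systematically shifts the peak position — up to several tens of
  milliseconds at 35 breaths/min. Each detected extremum is therefore
  re-estimated on the conditioned *pre-bandpass* trace by
  least-squares fitting a hinged parabola (separate curvatures left
  and right of a shared vertex) over ±25% of the gap to the
  neighbouring opposite extrema, with sub-sample interpolation of the
  residual minimum. A *symmetric* parabola is biased toward the
  flatter side when inspiratory and expiratory curvatures differ; the
  hinge model is not, and the wide fit window averages sensor noise
  out on the flat extrema of slow breaths. Boundary troughs without a
  peak on one side border featureless baseline, where the hinge is
  unconstrained; breaths leaning on them are dropped rather than
  emitted with degraded timing.

The upper band edge defaults to 1.0 Hz and may be raised to 1.4 Hz per
recording. `dominant_freq_bp_rule()` automates the choice: recordings
whose raw-IP spectrum peaks above 0.5 Hz get 1.4 Hz, because a
fast breather's second harmonic — needed for accurate phase timing —
lies above 1 Hz. The rule is deliberately simple and explicit; any
per-recording value in [1.0, 1.4] can be configured instead.

## Signal quality and outlier cascades

The SQI evaluates 32-s windows with 75% overlap. All breaths fully
inside a window are linearly time-normalized to the window's median IBI
and averaged into a template; the window passes when the coefficient of
variation of breath durations is ≤ 0.3, the mean Pearson correlation
against the template exceeds 0.7, and detected breaths cover at least
60% of the window. A breath is good if any window containing it passes.
The CoV criterion is applied to breath *durations* (amplitude is the
other defensible reading; durations were chosen because the downstream
features are timings, and the choice is configurable).

Three robust outlier filters follow, all based on the median absolute
deviation with the 1.4826 Gaussian-consistency factor (configurable to
raw MAD): 5 MAD over sliding 30-breath windows on {RR, Ti, Te}; 4 MAD
over 30-breath windows on the three unnormalized cumulative acoustic
intensities (breath, inspiratory, expiratory); and 5 MAD over the whole
recording's 32-s window means, refilled by linear interpolation over
window index with nearest-value edge extension. Windows are centered
and truncated at the edges. When a window's MAD is zero, any nonzero
deviation is flagged (zero-spread convention) — note the corollary that
*perfectly* clean, repetitive data self-flags numerically trivial
deviations, which is why realistic validation worlds include
physiological jitter.

## Acoustic features

Audio is resampled to 4 kHz and band-passed to 100–1000 Hz (below:
heart sounds; above: speech and room noise) with a zero-phase FIR. Per
phase segment, modified periodograms use 64-ms Hamming windows with 75%
overlap; each window's PSD is normalized by its maximum, integrated
over the four bands and divided by the 100–1000 Hz integral, and the
per-window SIs are averaged over the segment. Two deliberate choices:

- The bands are half-open [low, high) with the last closing at
  1000 Hz, an exact partition of [100, 1000] — hence the sum-to-one
  invariant tested at 1e-9.
- Normalization and the SI ratio are computed *per window, then
  averaged* (the alternative — normalize one averaged PSD — is a
  configuration away; the max-normalization cancels inside the ratio
  either way, and is retained for fidelity of any absolute outputs).
- FFT length equals the 256-sample window (no zero padding); the
  15.6 Hz bin width resolves all band edges, and bins are assigned to
  bands by centre frequency with rectangle-rule integration.

## Statistics

Per participant and time point, the windowed feature series is
aggregated by its mean. Paired contrasts use two-sided Wilcoxon
signed-rank tests (W = positive-rank sum; exact when no ties/zeros at
n ≤ 25, normal approximation otherwise; zeros dropped). Contrasts
against controls use two-sided rank-sum tests, reported as the rank sum
of the first-named group, with Benjamini–Hochberg adjustment applied
per feature across the *two* group comparisons (m = 2) — not across the
13 features; that matches the correction family the analysis defines,
and is configurable. PCA standardizes features to zero mean and unit
variance first (timing and SI features differ by orders of magnitude,
and a mixed-modality loading ranking is only meaningful on a common
scale), drops zero-variance features with a warning, and orients each
component so its largest-|loading| coefficient is positive.

## What the synthetic generator emulates — and what it does not

`generate_ip()` builds breaths as raised-cosine half-cycles of unequal
half-periods (rise over Ti, fall over Te) on a constant baseline, with
optional sinusoidal drift, additive Gaussian noise and multiplicative
step artifacts (emulating transients from loosened electrode leads —
magnitude, not shape, is what the removal rule keys on). The pipeline
must not and does not depend on this exact shape. `generate_lung_sound()`
produces band-limited Gaussian noise gated by phase with 50-ms
raised-cosine ramps (spectral-leakage hygiene), optional per-phase
subband spectral shaping, and optional tonal wheeze components at a
chosen SNR. `generate_cohort()` draws participant-level random effects
(shared across a patient's time points, making paired tests meaningful)
around group targets: an admission-like group (RR ≈ 35 breaths/min,
Ti/IBI ≈ 0.48, low-frequency-dominant spectra), a pre-discharge-like
group in between, and a control-like group (RR ≈ 22.4, Ti/IBI ≈ 0.41,
flatter spectra).

Stated-world defaults, chosen once: breath-timing jitter CV 3%
(tidal-breathing variability), between-participant RR variability 6%
(lognormal), subband-weight log-SD 0.10, impedance noise 0.02 Ω against
a 1 Ω excursion with 0.3 Ω slow drift, and 180-s recordings (long
enough for ~70–100 breaths per recording; full-length ~12-min
recordings would only slow the tests). The respiratory excursion
amplitude in ohms is a free parameter — nothing downstream depends on
its absolute scale. "Clean" recordings for the parameter-recovery
criteria are artifact-free and drift-free with noise at 0.2% of the
excursion: per-breath maximum-error bounds (RR within 1 breath/min at
60 breaths/min implies IBI to ~17 ms) sit at the resolution limit and
are statistically meaningless under percent-level noise on the flat
extrema of slow breaths.

The generator does **not** model electrode placement, posture,
multifrequency Cole impedance physics, realistic hospital noise,
coughs/speech, or sensor detachment; a green test therefore
establishes algorithmic correctness on plausible signals, not clinical
robustness.

## Known limitations

- The hinge refinement assumes locally convex extrema; pathological
  waveforms (plateaued breaths) fall back to the detected positions.
- Audio–IP clock alignment is assumed exact (shared device clock); no
  cross-modal alignment is estimated.
- Only one auscultation channel flows through the cohort analysis; the
  pipeline accepts any channel by label but performs no multichannel
  fusion.
- Rank-based tests switch to the tie-corrected normal approximation in
  the presence of ties; exactness claims hold only for tie-free data.
- Configuration serializes to JSON (not YAML) to avoid dependencies
  outside the guaranteed environment.
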