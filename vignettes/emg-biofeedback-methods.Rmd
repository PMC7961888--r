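---
title: "Methods: synthetic sEMG, the conditioning pipeline, and ratio-based biofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic sEMG, the conditioning pipeline, and ratio-based biofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfb)
```

This vignette is the package's own account of its models and the choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` do not themselves compute.

## 1. The signal model

Surface EMG is modelled phenomenologically, not physiologically: each
channel is a white Gaussian process shaped to a physiological band and
amplitude-modulated by the activation level,

$$ x(t) = \big(\sigma_0 + a(t)\,\sigma_{\max}\big)\, n_B(t), $$

where $n_B$ is unit-variance band-limited noise, $a(t) \in [0,1]$ the
volitional activation, $\sigma_0$ the electrode-referred noise floor and
$\sigma_{\max}$ the full-activation amplitude. This reproduces the
second-order statistics (spectrum, rectified-mean scaling) that every
downstream stage consumes; it deliberately omits motor-unit recruitment,
firing synchronization, electrode geometry and fatigue, which none of the
implemented statistics are sensitive to.

Choices and defaults:

* **Shaping band 20–450 Hz** — the conventional sEMG energy band. The
  shaping filter is a 6th-order Butterworth bandpass: order 4 leaves ≈5.6%
  of the noise power in the skirts, violating the generator's own
  spectral contract (≥95% of power in band); order 6 keeps ≈95.8% in band
  and remains numerically comfortable (largest pole modulus ≈0.985).
* **Noise floor $\sigma_0 = 20\ \mu V$, full activation
  $\sigma_{\max} = 1\ mV$** (electrode-referred RMS). The hardware noise
  floor is not documented for the low-cost sensor, so $\sigma_0$ is a free
  parameter; 20 µV is a realistic surface-recording floor and 1 mV a
  typical strong voluntary contraction. The ratio (SNR 50:1) drives the
  small positive bias of rest-state envelopes (≈0.02 normalized) and the
  ≤0.01 bias of recovered extensor ratios.
* **Front end** — gain 500 V/V, supply 3.3 V (offset 1.65 V), saturation at
  the rails, 12-bit quantization, 2000 Hz. With a zero envelope and
  $\sigma_0 = 0$ the output is exactly the midpoint code 2048. At full
  activation the post-gain RMS is 0.5 V, so rail clipping affects ≈0.1% of
  samples — the same mild saturation real hardware shows.
* **Crosstalk** — linear pre-gain mixing of each channel into the other,
  default 0; a robustness knob, not a claim about electrode placement.
* **Force coupling** — grip force is a first-order lag
  ($\tau = 0.1$ s) of the weighted activation sum plus Gaussian noise
  (SD 0.01 MVC), clipped at zero. The discretization is exact
  ($f_k = e^{-\Delta t/\tau} f_{k-1} + (1 - e^{-\Delta t/\tau})\,d_k$), so
  the step response hits $(1 - e^{-1})L$ at exactly $t = \tau$ — the
  closed form the tests assert. Default weights 0.5/0.5 make equal
  co-activation at level $L$ produce force $L$, which is the simplest
  world in which the ramp-phase EMG–force regression behaves like the
  published validation task.
* **Randomness** — every public generator takes a caller seed; internal
  sub-streams derive from it through a deterministic child-seed map, and
  the caller's global RNG state is always restored. Identical inputs and
  seed give bit-identical recordings.

## 2. The conditioning pipeline

The chain is bandpass → rectify → normalize → smooth.

* **Filter realization.** Only the band (150–450 Hz online/offline; a
  15–450 Hz variant is reported as equivalent for these statistics) is
  prescribed by practice; the realization is a 4th-order Butterworth
  bandpass designed by bilinear transform. Offline mode subtracts the
  channel mean and filters forward–backward (zero phase): a constant
  input maps exactly to zero, and adding any offset leaves the envelope
  unchanged to machine precision. Streaming mode is strictly causal.
* **Zero-phase gain vs causal gain.** Forward–backward filtering applies
  $|H|^2$ where a causal pass applies $|H|$, so the two modes pass
  slightly different broadband energy (≈10% in rectified mean over the
  150–450 band). This cancels when calibration uses the same mode as
  processing — which the package does, as any deployed system calibrates
  through its own pipeline. The cross-mode agreement test therefore
  compares mode-matched envelopes, and compensates the trailing smoother's
  deterministic group delay (half the 250-ms window) before comparing
  windowed means; residual disagreement on steady epochs is ≈2%.
* **Windows.** 250-ms Hann for the display envelope, 1-s boxcar for the
  isometric validation analysis, both normalized to unity DC gain.
  Offline windows are centred with reflect padding; streaming windows are
  trailing with zero initialization, the first window flagged transient.
* **Calibration** takes, per channel, the maximum 250-ms trailing moving
  average of the rectified filtered grip recording. The alternative
  statistic (mean during the grip) is available as
  `pipeline_config(calib_stat = "mean")`; the windowed maximum is the
  default because it is what normalizes the live feedback range. A channel
  whose amplitude is below 3× the quietest windowed level of the same
  recording fails calibration by name — an automated stand-in for the
  clinician's visual signal check.
* **Normalization does not clip.** Values above 1 (activity beyond the
  reference grip) are preserved; clipping would bias the extensor ratio
  toward 0.5.
* **Streaming chunk-exactness.** The streaming processor carries the
  difference-equation state (trailing inputs/outputs) and the smoother
  tail across chunks, so chunked processing equals one-shot causal
  processing exactly, not approximately.

## 3. The games

* **Extensor ratio.** $ER = e/(e+f)$ on trial-window means (2 s from each
  movement-attempt onset; the live-game epoch is the same window, length
  configurable, since no separate real-time epoch is prescribed). When
  $e + f < 10^{-6}$ normalized units the ratio is undefined; it is
  reported as 0.5 — no activity is indistinguishable from perfect
  co-activation in this statistic — with a `degenerate` flag preserved
  through logs so such trials are auditable.
* **Score table.** Bin edges are lower-exclusive/upper-inclusive. The
  published table's top bin ends at 0.99, leaving (0.99, 1] unassigned;
  scoring a perfect ratio as *nothing* is clearly unintended, so the top
  bin extends to 1. ER exactly 0 falls to the bottom bin.
* **Blinko.** The chip physics are unspecified beyond "any number of
  paths"; the package uses `n_rows` independent ±half-slot steps with
  reflecting walls. This gives an exactly enumerable null (the tests
  brute-force all $2^{n}$ paths) while reproducing the qualitative
  behaviour: a symmetric spread around the ER-mapped start slot. The
  SkeeBall ring animation is reduced to its points value.

## 4. Protocols

Ramp–hold validation: 5 s ramp to 25% MVC, 5 s hold, 7 s rest — a 17-s
sweep — repeated 12 times with no extra inter-trial gap (the rest phase is
the gap). For analysis the first 0.5 s of each hold is trimmed
(configurable) to avoid ramp overshoot, a detail the task description
leaves open. Training sessions: 5 blocks × 20 repetitions with a 2-s trial
window, 3-s inter-trial rest (unstated; chosen as a realistic pace) and
60 s between blocks (1–2 min in practice).

## 5. Statistics

* **Pairing unit.** Device comparisons pair per-trial mean ER (n = 12
  pairs) rather than per-time-point samples, which would inflate degrees
  of freedom through autocorrelation; pointwise series remain available
  for distribution plots.
* **Regression direction.** Force is regressed on normalized activity
  (activity as predictor): the question is how much force variance the
  EMG explains.
* **p-values** are two-sided throughout; no multiple-testing correction is
  applied anywhere, matching the analysis practice the package mirrors.
* **Exclusions** are operationalized as explicit rules (missing channel,
  calibration failure, rest-envelope mean above a ceiling of 0.2
  normalized units) because only the outcome, not the rule, is prescribed;
  excluded sessions never enter summaries or trends. Trends over all
  sessions can be obtained by clearing the flags.
* **Degenerate trend fields** (zero variance) return `rho = NA` with a
  `degenerate` flag rather than an error, so a batch report survives a
  pathological field.
* Standard fits go through base R (`t.test`, `lm`, `cor.test`) behind the
  package's interfaces; the tests check them against hand-computed
  textbook and normal-equation oracles.

## 6. What a green test does and does not establish

The generator's stated world — stationary band-limited noise, linear
amplitude modulation, linear force coupling, a stable 50:1 SNR — is enough
to exercise every computation: recovery of activation ratios as ER within
±0.05, score-table frequencies within 1%, type-I error of the paired t,
detection of a 0.5→0.7 individuation drift over 40 sessions. It does
*not* establish robustness to the things real home recordings add:
electrode repositioning across sessions, motion artifact, mains
interference (no notch filter is implemented), impedance drift, fatigue
spectral compression, or genuinely nonstationary co-activation. Results on
synthetic data bound the software, not the sensor.

## 7. Numerical notes

* Filter design was cross-checked against an independent DSP
  implementation to 1e-15 in the coefficients during development; the test
  suite keeps an analytic frequency-response oracle (band-edge gain
  $1/\sqrt{2}$, DC null) so the check does not depend on external
  software.
* The 8th-degree transfer-function polynomials are numerically benign at
  these band/rate ratios; a second-order-sections realization would be the
  next step only if the band were pushed far below 150 Hz at 2000 Hz
  sampling.
* Zero-rise activation steps, empty segment lists, silent channels,
  constant predictors and zero-variance differences all have defined
  behaviour (exact step, all-zero trace, named calibration failure, named
  errors) and are covered by tests.
* Counts↔volts convention: `volts = counts × supply_v / (2^bits − 1)`,
  stated in every file header; normalization cancels units, and the
  counts and volts pipelines agree to 1e-9 relative in the tests.
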