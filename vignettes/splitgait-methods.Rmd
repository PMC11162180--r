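---
title: "Methods: stride-level behavior and gait-cycle spectral analysis of split-belt adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level behavior and gait-cycle spectral analysis of split-belt adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgait)
```

## What the package computes

splitgait analyses split-belt treadmill adaptation experiments in which the
left and right belts are driven at different speeds to perturb gait
symmetry. It covers two layers of analysis and a synthetic-data generator
that makes both testable without laboratory recordings.

**Behavioral layer.** Gait events are detected from per-belt vertical
ground-reaction forces (GRF); from the ankle-marker anterior-posterior
(AP) positions the package computes, per stride,

* step length asymmetry
  $\mathrm{SLA} = \dfrac{SL_{fast} - SL_{slow}}{SL_{fast} + SL_{slow}}$,
  where the *fast* step length is the AP distance between the ankle
  markers at right foot contact (the right belt is the fast belt) and the
  *slow* step length the distance at left foot contact;
* belt speeds, estimated as the mean absolute AP marker velocity during
  each foot's stance, and belt symmetry
  $\mathrm{BS} = \dfrac{v_{fast} - v_{slow}}{v_{fast} + v_{slow}}$;
* asymmetric-stride flags: a stride is a stepping error when
  $|\mathrm{SLA}| > \mu_{ref} + 2\sigma_{ref}$, with the reference moments
  taken over the last 30 strides of the tied-belt block preceding the
  gradual perturbation;
* steady-state and performance statistics (strides to steady state for the
  abrupt schedule, percent asymmetric strides for the gradual one, both
  min-max normalized over the cohort and inverted, then related by
  ordinary least squares).

**Spectral layer.** Source-level neural time series are decomposed with
complex Morlet wavelets on a 2–50 Hz grid; per-stride log-power maps are
baseline-normalized with each stride's own full-cycle mean (per
frequency), linearly time-warped so that every stride's right foot
contact (RFC), left foot-off (LFO), left foot contact (LFC) and right
foot-off (RFO) land on the group-median (canonical) cycle latencies, and
averaged first within subject and then across subjects with equal subject
weights. Condition contrasts are tested with a paired cluster-based
permutation test with maximum Cohen's *d* effect sizes and bootstrap
confidence intervals.

## The protocol and the synthetic generator

`split_belt_protocol()` encodes the session design: tied familiarisation
blocks at 0.6, 1.2 and 0.9 m/s, a 15-min abrupt 2:1 split (transitions at
0.2 m/s²), a 10-min tied washout, a 5-min gradual ramp in which the right
belt climbs 0.9→1.2 m/s while the left falls 0.9→0.6 m/s (0.001 m/s² per
belt), a 2-min 2:1 hold, and a final 5-min tied block. The tied
familiarisation blocks have no published duration; 3 min each keeps the
session under an hour and leaves comfortably more than the 30 strides the
reference windows need. Belt speed is piecewise linear, so abrupt
transitions are short ramps and the commanded profile is continuous.

`simulate_session()` produces the raw signals of one subject walking a
schedule:

* **Adaptation model.** A single error-driven state: on stride $k$ the
  perturbation $p_k$ is the commanded belt symmetry at the stride
  midpoint, the stepping error is $e_k = p_k - x_k + \varepsilon_k$, the
  state updates $x_{k+1} = x_k + \eta e_k$, and the stride's SLA equals
  $e_k$. Under an abrupt step $p_0$ this yields the closed form
  $\mathrm{SLA}_k = p_0(1-\eta)^k$; a return to tied belts produces an
  after-effect of $-x$ that washes out at the same rate; and under the
  gradual ramp the error is a small, lagging tracking error — the
  qualitative signatures of abrupt vs gradual adaptation. The learning
  rate defaults to $\eta = 0.25$ per stride with execution noise
  SD 0.012; the literature reports no quantitative rate for this
  protocol, so $\eta$ is a free parameter chosen to give a washout over a
  few tens of strides, and nothing downstream depends on its exact value.
* **Cadence.** A nominal 1.1 s gait cycle with 20 ms Gaussian jitter;
  events are placed at fixed cycle fractions (LFO 12 %, LFC 50 %,
  RFO 62 %), i.e. each foot is in stance about 62 % of the cycle.
* **GRF.** Each stance is a two-hump waveform: raised-cosine rise and
  fall over the first and last 16 % of stance, with loading and push-off
  peaks at the set peak force and a mid-stance valley at 75 % of it. The
  slow edges keep the waveform essentially band-limited below the 6 Hz
  detection filter, so the 10 N threshold crossing survives zero-phase
  filtering with a shift well inside the ±15 ms the tests allow. Only
  the threshold behaviour matters downstream; the waveform's exact shape
  is a generator choice.
* **Markers.** During stance the ankle marker is carried backwards at the
  commanded belt speed (its integral); during swing it follows a cubic
  Hermite path whose end velocities match the belt on both sides, so the
  trajectory is C¹ and the step lengths measured at the true contact
  times reproduce the model SLA to the interpolation tolerance (≤ 1e-3).
  The step-length sum is fixed at 0.99 m (nominal cycle duration times
  the 0.9 m/s mean speed), which keeps the net walkway drift near zero.
* **Sources.** Per region, 1/f pink noise plus one Hann-windowed burst
  per stride at the band centre frequency, centred at a fixed cycle
  fraction, with amplitude `baseline + gain * |SLA|`. The default spec
  places a theta burst (4–7 Hz) at 40 % of the cycle — right-leg single
  support, just before left foot contact — and an alpha burst late in the
  cycle for a posterior parietal source, mirroring the kind of
  gait-phase-locked, error-modulated activity the analysis is meant to
  detect. Same configuration and seed give bit-identical sessions; a
  cohort draws one sub-seed per subject from the master seed, so subject
  *i*'s data do not depend on the cohort size.

What the generator does **not** emulate: scalp-level volume conduction and
channel mixing, motion or muscle artifacts, EMG, non-stationary cadence
drift, or any coupling from neural state back to behaviour. Passing the
recovery tests therefore shows the pipeline recovers effects of the
assumed structure at realistic SNR — not that real EEG meets those
assumptions.

## Numerical and design choices

* **Event detection.** Forces are low-pass filtered (zero-phase
  second-order Butterworth, 6 Hz) and regridded to 512 Hz. Edge
  transients are suppressed with odd-reflection padding; regridding uses
  cubic-spline interpolation, which is delay-free and exact for a signal
  band-limited far below both rates (a polyphase resampler was rejected
  because its uncompensated group delay, ~5 ms here, would eat a third of
  the event-timing budget). Contacts are upward 10 N crossings, foot-offs
  downward ones. Debounce: a crossing closer than 100 ms to the previous
  kept crossing delimits a spurious short phase and cancels both
  crossings, which survives both chatter and brief dropouts. Strides run
  RFC-to-RFC; a stride is kept only when exactly LFO < LFC < RFO occur
  inside it, otherwise it is dropped and logged. Interactive misstep
  correction is not reproducible and is reduced to this flag-and-drop
  rule.
* **Abnormal latencies.** Strides whose stride time deviates more than
  4 SD from the session mean are flagged (never removed); a zero-SD
  latency distribution defines z = 0, so uniform sessions are never
  flagged. Step-time screening is available via `basis = "step"`; stride
  time is the default because SLA is tabulated per stride.
* **Belt-series cleaning.** Missing values are linearly interpolated; a
  6-tap moving average (coefficients 1/6) smooths the series, with
  shorter windows at the start so constants pass unchanged; elements more
  than 3 local SD from the local mean of a 6-element window (3 back,
  2 ahead) are replaced by the mean of the nearest valid neighbours on
  each side.
* **Median split.** Asymmetric strides strictly above the median |SLA| of
  the asymmetric strides are `large`; ties and the median element are
  `small`. Deterministic and order-independent.
* **Steady state.** Mean and SD both come from the last 30 strides of the
  phase (the wording "2 SD of the steady state" names no window; using
  the same window keeps the band self-consistent), counted in strides,
  band inclusive, run length 10.
* **Binning.** Pre-adaptation bins are the last 30 strides before each
  perturbation onset. The ramp holds ≈ 270 strides; early/mid/late ramp
  are the first, centre and last 30-stride windows, the middle one
  centred on the ramp midpoint (clamped so the three bins never overlap).
  The 2:1 bins start at the first stride whose entire duration falls
  after the belts reach terminal speed. Post blocks use strides 1–10,
  11–40 and the last 30. In this protocol the pre-gradual reference (the
  30 strides before the ramp) coincides with the tail of the first post
  block; reference labels are assigned last and win, so every stride
  carries exactly one label.
* **SLA normalization.** Subtracting the subject's pre-abrupt tied-belt
  mean is the default for cross-subject comparison; the asymmetric-stride
  criterion deliberately uses the pre-gradual window instead, because
  behavioural after-effects need not have washed out fully by then.
* **Wavelets.** Cycles grow as $n(f) = 3 (f/2)^{0.2}$ — 3 cycles at 2 Hz,
  ≈ 5.7 at 50 Hz — one concrete reading of the common "[3, 0.8]"
  convention, in which the second parameter shrinks the high-frequency
  window relative to a constant-cycle wavelet. Filters are built
  analytically in the frequency domain (Gaussian of SD
  $1/(2\pi\sigma_t)$ around each centre frequency, unit peak gain,
  positive frequencies only) and applied by FFT with padding factor 2;
  power is $10\log_{10}|W|^2$. The grid is 49 log-spaced frequencies over
  2–50 Hz. Strides without wavelet context (three time-SDs of the longest
  wavelet, ≈ 0.72 s) on both sides are dropped and logged.
* **Baseline.** Per frequency, each stride's own mean log power across
  its cycle is subtracted ("full-trial" single-trial baseline); any
  per-stride gain error is removed exactly, which makes condition
  contrasts invariant to per-stride dB offsets. A divisive variant
  (also scaling by the within-stride SD) sits behind
  `divisive = TRUE`; subtraction-only is the default because that is the
  operation the baseline definition actually names.
* **Time-warp.** Piecewise-linear and monotone by construction, with the
  canonical grid at 200 columns per cycle (0.5 % resolution, comfortably
  finer than the ±1.5 % localisation the tests demand); values are
  linearly interpolated. Canonical latencies are pooled medians over all
  strides of all subjects.
* **Cluster test.** Paired t per pixel; two-tailed cluster-forming
  threshold p < 0.05 (the toolbox default; only the final threshold is
  published); clusters under 4-connectivity separately for positive and
  negative t; statistic = sum of t (`maxsum`); null = maximum absolute
  cluster statistic over random within-subject sign flips; Monte-Carlo
  $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$, so p is never zero.
  Significance threshold 0.05, default 15 000 permutations (tests use
  reduced counts). Cluster size and 8-connectivity are available behind
  flags. Each contrast is tested independently, mirroring the
  per-subcondition design. Effect size is the maximum |d| over the
  cluster's pixels (sign kept; zero-SD pixels skipped), with a
  subject-level percentile bootstrap CI (default 3 000 resamples;
  single-subject resamples redrawn).
* **Formats.** Tables are TSV with full-precision numerics; schedules,
  configurations and run manifests are JSON; time-frequency maps live in
  a directory container (JSON metadata plus one TSV matrix per map).
  Every stochastic stage takes an explicit seed and the manifest records
  all parameters, so a run is reproducible bit-for-bit.

## What the tests demonstrate, at which problem sizes

The package's statistical guarantees are exercised at desk scale:

* the null calibration of the cluster test uses 200 replicates of
  20 subjects on 25 × 100 maps with 1 000 permutations, and checks that
  the any-significant-cluster rate stays within two binomial standard
  errors of the nominal 0.05 (the max-cluster null is conservative);
* effect recovery uses 50 seeded cohorts of 20 subjects walking a
  shortened tied-plus-ramp schedule (40 s tied, 104 s ramp; GRF 250 Hz,
  markers 50 Hz, sources 128 Hz), analysed at a reduced spectral scale
  (30 frequency bins, 100 cycle columns, unpadded FFTs — the method is
  unchanged), with the theta burst gain calibrated once so the per-pixel
  paired effect in the injected 4–7 Hz × 20 %-cycle window is d ≈ 1; the
  full pipeline must localise a significant cluster covering at least
  half the window in ≥ 80 % of cohorts, and must not localise one there
  in ≥ 95 % of gain-zero cohorts (isolated chance clusters elsewhere are
  governed by the family-wise-error calibration);
* stride-level statistics (steady state, error flags, median split,
  belt-series cleaning, maximum Cohen's d) are checked for exact
  agreement with independent brute-force implementations on 1 000 random
  instances each;
* module tests run a shortened full protocol (40 s tied blocks, 60 s
  abrupt split, 90 s washout, 110 s ramp, 70 s hold, 85 s post) so every
  bin exists while a session simulates in a few seconds.

These sizes are the package's own test design; the exported defaults
(full protocol, 15 000 permutations, 3 000 bootstrap resamples) match the
study-scale analysis.

## Known limitations

* Real force plates produce cross-steps, missing strides and drift that
  the flag-and-drop rules only approximate; the generator does not
  emulate cross-stepping at all.
* The event-timing bias of threshold detection after 6 Hz filtering
  (≈ 10 ms, symmetric between contact and off) slightly widens measured
  stance relative to truth; it cancels in stride durations and in the
  warped cycle but not in raw event latencies.
* Belt-speed estimation from marker velocity inherits marker noise and
  the smoothing window's phase-boundary memory (the first ~6 strides
  after a speed change are biased toward the previous block).
* The published belt-symmetry value 0.55 ± 0.08 during initial gradual
  errors is not reproducible from the printed speeds (a 0.23 m/s
  difference over a 1.8 m/s sum gives ≈ 0.13 under the belt-symmetry
  formula); the package implements the formula literally and makes no
  attempt to match that number.
* Percentile bootstrap CIs for a maximum over pixels are biased upward
  for small clusters; they are reported as descriptive uncertainty, not
  as a test.
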