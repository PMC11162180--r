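# splitgait

Stride-level behavior and gait-cycle spectral analysis of split-belt
treadmill adaptation experiments, with a synthetic-session generator that
makes the whole pipeline testable end-to-end without laboratory data.

Split-belt treadmills drive the two belts at different speeds to perturb
gait symmetry. Subjects gradually reduce the resulting stepping errors
(adaptation) and overshoot in the opposite direction when the belts are
retied (after-effects). The package is written for movement-neuroscience
groups who record ground-reaction forces, ankle-marker kinematics and
source-level neural time series during such protocols and want a
reproducible, scriptable version of the standard analysis chain.

## What it computes

**Behavior, per stride.** Gait events (RFC, LFO, LFC, RFO) from a 10 N
threshold on low-pass-filtered (6 Hz, zero-phase) vertical ground-reaction
forces; step lengths from the ankle-marker anterior-posterior distance at
each foot contact; step length asymmetry and belt symmetry

$$\mathrm{SLA}=\frac{SL_{fast}-SL_{slow}}{SL_{fast}+SL_{slow}},\qquad
\mathrm{BS}=\frac{v_{fast}-v_{slow}}{v_{fast}+v_{slow}},$$

asymmetric-stride (stepping-error) flags,
$|\mathrm{SLA}|>\mu_{ref}+2\sigma_{ref}$ over a 30-stride reference
window; strides-to-steady-state; a large/small error median split; and
cohort performance scores with an OLS regression between abrupt and
gradual adaptation performance.

**Spectra, per gait cycle.** Complex Morlet decompositions (cycles
$3\,(f/2)^{0.2}$, 49 log-spaced frequencies over 2–50 Hz), single-trial
full-cycle baseline in dB, piecewise-linear time-warping of every stride
onto the canonical (group-median) event latencies, subject- then
group-level averaging, and paired cluster-based permutation tests
(maxsum statistic, two-tailed cluster-forming p < 0.05, Monte-Carlo p
with the +1 correction) with maximum Cohen's *d* per significant cluster
and bootstrap confidence intervals.

**Synthesis.** `simulate_session()` generates belt-speed schedules,
ground-reaction forces, markers and source signals from an error-driven
state-space model of adaptation (`x <- x + eta * e`, SLA = error) with
gait-phase-locked oscillatory bursts whose amplitude grows with the
stride's |SLA| — the signal structure the downstream analysis assumes,
with ground truth returned for every stride.

## Worked example

```r
library(splitgait)

sched <- split_belt_protocol()
ramp  <- sched[sched$phase == "ramp", ]
abs(ramp$right_end - ramp$right_start) / ramp$duration_s
#> [1] 0.001                    # m/s^2, per belt
ramp$right_end / ramp$left_end
#> [1] 2                        # terminal 2:1 ratio
```

A ten-subject synthetic cohort on a shortened protocol (40 s tied blocks,
110 s ramp, 70 s hold), with a theta burst at 40 % of the gait cycle whose
amplitude tracks stepping-error size, analysed end to end:

```r
sched <- split_belt_protocol(pre_block_s = 40, abrupt_split_s = 60,
  post1_s = 90, ramp_s = 110, split_hold_s = 70, post2_s = 85,
  sample_rate_grf = 500, sample_rate_sources = 256)
spec <- tibble::tibble(region = "left_acc", band_lo = 4, band_hi = 7,
  gait_phase_center = 40, phase_width = 20, gain_vs_error = 12,
  baseline_amplitude = 0.5)
cfg <- synthetic_config(n_subjects = 10, adaptation_rate = 0.1,
                        burst_spec = spec, seed = 42)
pc  <- pipeline_config(schedule = sched, synthetic = cfg,
                       regions = "left_acc",
                       contrasts = c("mid_ramp", "late_split"),
                       n_perm = 1000, n_boot = 300, seed = 42)
report <- run_pipeline(pc)
report
#> <splitgait_report> 10 subject(s), regions: left_acc
#>   left_acc / mid_ramp: 1 significant cluster(s)
#>   left_acc / late_split: 0 significant cluster(s)

tidy(report$contrasts$left_acc$mid_ramp) |> dplyr::filter(significant)
#> # A tibble: 1 × 6
#>   cluster  sign n_pixels  stat        p significant
#>     <int> <dbl>    <int> <dbl>    <dbl> <lgl>
#> 1      10     1      711 2835. 0.000999 TRUE

dplyr::bind_rows(report$contrasts$left_acc$mid_ramp$effect_sizes)
#> # A tibble: 1 × 4
#>   cluster max_d d_lower d_upper
#>     <int> <dbl>   <dbl>   <dbl>
#> 1      10  2.87    2.73    10.9

round(report$latencies, 1)
#>  rfc  lfo  lfc  rfo
#>  0.0 13.8 50.0 63.8
```

The mid-ramp contrast — where the lagging tracking error of gradual
adaptation is largest — shows a positive theta-band cluster
(synchronization relative to the pre-gradual reference) with p ≈ 0.001
and a maximum paired Cohen's d of 2.9; by the late 2:1 hold the model has
adapted, errors are small, and no cluster survives. `autoplot()` on any
condition map or cluster result draws the corresponding time-frequency
figure, with dashed lines at the canonical event latencies printed above.

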