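# Shared fixtures. Sessions are generated in code and cached for the test
# run, so expensive simulations happen once.

# shortened full protocol: every phase present with just enough strides for
# the 30-stride bin structure
short_schedule <- function(grf_rate = 500, marker_rate = 100,
                           source_rate = 256) {
  split_belt_protocol(
    pre_block_s = 40, abrupt_split_s = 60, post1_s = 90,
    ramp_s = 110, split_hold_s = 70, post2_s = 85,
    sample_rate_grf = grf_rate, sample_rate_markers = marker_rate,
    sample_rate_sources = source_rate
  )
}

# minimal tied + ramp schedule for spectral power studies: one tied block
# feeding the pre-gradual reference, then a full-length gradual ramp
ramp_only_schedule <- function(grf_rate = 250, marker_rate = 50,
                               source_rate = 128,
                               tied_s = 40, ramp_s = 104) {
  phases <- tibble::tibble(
    phase = c("pre_medium", "ramp"),
    duration_s = c(tied_s, ramp_s),
    left_start = c(0.9, 0.9), left_end = c(0.9, 0.6),
    right_start = c(0.9, 0.9), right_end = c(0.9, 1.2)
  )
  new_belt_schedule(phases, sample_rate_grf = grf_rate,
                    sample_rate_markers = marker_rate,
                    sample_rate_sources = source_rate)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fixture_session <- function() {
  cached("session", function() {
    simulate_session(short_schedule(), synthetic_config(seed = 7))
  })
}

fixture_config <- function() {
  pipeline_config(schedule = short_schedule(),
                  synthetic = synthetic_config(seed = 7),
                  n_perm = 500)
}

fixture_stride_table <- function() {
  cached("stride_table", function() {
    suppressMessages(stride_table(fixture_session(), fixture_config()))
  })
}

# generator settings used in the spectral power-recovery studies: slow
# learning keeps ramp errors sizeable, and the theta burst gain is the
# generator's calibration for a per-pixel paired effect of d ~ 1 in the
# injected window
recovery_config <- function(seed, gain = 12, n_subjects = 1) {
  spec <- tibble::tibble(
    region = "left_acc", band_lo = 4, band_hi = 7,
    gait_phase_center = 40, phase_width = 20,
    gain_vs_error = gain, baseline_amplitude = 0.5
  )
  synthetic_config(n_subjects = n_subjects, adaptation_rate = 0.1,
                   sla_noise_sd = 0.012, burst_spec = spec, seed = seed)
}
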