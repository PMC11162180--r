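#' Default gait-phase-locked oscillatory burst specification
#'
#' One row per simulated source region. Each stride receives a Hann-windowed
#' sinusoidal burst at the band centre frequency, centred at
#' `gait_phase_center` percent of the gait cycle, with amplitude
#' `baseline_amplitude + gain_vs_error * |SLA|` for that stride. The
#' defaults place a theta burst in right-leg single support (just before
#' left foot contact) for a midline-frontal "acc" source and an alpha burst
#' late in the cycle for a posterior parietal source.
#'
#' @return Tibble with columns `region`, `band_lo`, `band_hi` (Hz),
#'   `gait_phase_center`, `phase_width` (% of cycle), `gain_vs_error`
#'   (amplitude per unit |SLA|) and `baseline_amplitude` (a.u.).
#' @export
default_burst_spec <- function() {
  tibble::tibble(
    region = c("left_acc", "posterior_parietal"),
    band_lo = c(4, 8),
    band_hi = c(7, 12),
    gait_phase_center = c(40, 75),
    phase_width = c(20, 20),
    gain_vs_error = c(6, 3),
    baseline_amplitude = c(0.6, 0.6)
  )
}

#' Configuration of the synthetic split-belt session generator
#'
#' @param n_subjects Number of subjects in a simulated cohort.
#' @param adaptation_rate Learning rate eta of the error-driven adaptation
#'   state, in (0, 1) per stride.
#' @param sla_noise_sd SD of the per-stride execution noise added to the
#'   stepping error (unitless SLA units).
#' @param grf_peak_force Peak vertical ground-reaction force (N).
#' @param burst_spec Burst specification, see [default_burst_spec()].
#' @param pink_noise_exponent Spectral exponent of the 1/f^a background in
#'   the source signals.
#' @param source_noise_sd SD of the background noise in the source signals
#'   (a.u.).
#' @param cycle_s Nominal gait-cycle duration (s).
#' @param cycle_jitter_sd SD of the Gaussian jitter on cycle duration (s).
#' @param step_length_sum Sum of fast and slow step lengths (m), held fixed
#'   so that step lengths follow directly from the per-stride SLA.
#' @param seed Master seed; per-subject streams are spawned from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 1,
                             adaptation_rate = 0.25,
                             sla_noise_sd = 0.012,
                             grf_peak_force = 800,
                             burst_spec = default_burst_spec(),
                             pink_noise_exponent = 1,
                             source_noise_sd = 1,
                             cycle_s = 1.1,
                             cycle_jitter_sd = 0.02,
                             step_length_sum = 0.99,
                             seed = 1L) {
  if (!is.numeric(adaptation_rate) || adaptation_rate <= 0 ||
      adaptation_rate >= 1) {
    abort("adaptation_rate must lie strictly inside (0, 1)")
  }
  if (sla_noise_sd < 0 || cycle_jitter_sd < 0 || source_noise_sd < 0) {
    abort("noise standard deviations must be >= 0")
  }
  burst_spec <- tibble::as_tibble(burst_spec)
  if (nrow(burst_spec) &&
      (any(burst_spec$band_lo < 2) || any(burst_spec$band_hi > 50) ||
       any(burst_spec$band_lo >= burst_spec$band_hi))) {
    abort("burst bands must lie within 2-50 Hz with band_lo < band_hi")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    adaptation_rate = adaptation_rate,
    sla_noise_sd = sla_noise_sd,
    grf_peak_force = grf_peak_force,
    burst_spec = burst_spec,
    pink_noise_exponent = pink_noise_exponent,
    source_noise_sd = source_noise_sd,
    cycle_s = cycle_s,
    cycle_jitter_sd = cycle_jitter_sd,
    step_length_sum = step_length_sum,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Gait-event phase fractions within a stride (RFC at 0).
# Left foot-off ends the first double support, left foot contact falls at
# mid-cycle, right foot-off ends the second double support; each foot is in
# stance ~62% of the cycle.
event_phase_fractions <- c(lfo = 0.12, lfc = 0.50, rfo = 0.62)

#' Simulate the per-stride adaptation state and step length asymmetry
#'
#' Error-driven state-space model of split-belt adaptation. The perturbation
#' p experienced on a stride is the commanded belt symmetry
#' (fast - slow)/(fast + slow) at the stride midpoint. The stepping error is
#' e = p - x + noise, the learned state updates x <- x + eta * e, and the
#' stride's step length asymmetry equals e. Under an abrupt step input p0
#' and zero noise this yields the geometric decay SLA_k = p0 (1 - eta)^k,
#' and a return to tied belts produces an after-effect of -x that washes
#' out at the same rate.
#'
#' @param schedule A `belt_schedule`.
#' @param cfg A `synthetic_config`.
#' @return Tibble with one row per stride: `stride_index`, event times
#'   `rfc_s`, `lfo_s`, `lfc_s`, `rfo_s`, `stride_end_s`, `cycle_s`,
#'   commanded `belt_left`, `belt_right`, perturbation `p`, adaptation
#'   state `x`, and `sla`.
#' @export
simulate_strides <- function(schedule, cfg) {
  total <- protocol_duration(schedule)
  eta <- cfg$adaptation_rate
  # stride start times: jittered nominal cadence covering the session
  n_max <- ceiling(total / max(cfg$cycle_s - 4 * cfg$cycle_jitter_sd, 0.3)) + 2L
  cyc <- cfg$cycle_s + rnorm(n_max, 0, cfg$cycle_jitter_sd)
  cyc <- pmax(cyc, 0.3)
  starts <- c(0, cumsum(cyc))
  keep <- which(starts + c(cyc, Inf)[seq_along(starts)] <= total)
  starts <- starts[keep]
  cyc <- cyc[seq_along(starts)]
  n <- length(starts)
  if (n < 2L) abort("schedule too short to hold a single stride")

  mid <- starts + cyc / 2
  sp <- belt_speed_at(schedule, mid)
  p <- compute_belt_symmetry(sp$right, sp$left)
  p[is.na(p)] <- 0

  noise <- rnorm(n, 0, cfg$sla_noise_sd)
  x <- numeric(n)
  e <- numeric(n)
  xk <- 0
  for (k in seq_len(n)) {
    x[k] <- xk
    e[k] <- p[k] - xk + noise[k]
    xk <- xk + eta * e[k]
  }

  tibble::tibble(
    stride_index = seq_len(n),
    rfc_s = starts,
    lfo_s = starts + event_phase_fractions[["lfo"]] * cyc,
    lfc_s = starts + event_phase_fractions[["lfc"]] * cyc,
    rfo_s = starts + event_phase_fractions[["rfo"]] * cyc,
    stride_end_s = starts + cyc,
    cycle_s = cyc,
    belt_left = sp$left,
    belt_right = sp$right,
    p = p,
    x = x,
    sla = e
  )
}

# Two-hump stance template on u in [0, 1]: raised-cosine rise/fall over the
# first/last `edge` fraction, plateau modulated to peak in early and late
# stance with a mid-stance valley. The rise is kept slow enough that the
# waveform is nearly band-limited below the 6 Hz detection filter, so the
# low-threshold crossing survives zero-phase filtering with little shift.
stance_template <- function(u, edge = 0.16) {
  w <- rep(1, length(u))
  lo <- u < edge
  hi <- u > 1 - edge
  w[lo] <- 0.5 - 0.5 * cos(pi * u[lo] / edge)
  w[hi] <- 0.5 - 0.5 * cos(pi * (1 - u[hi]) / edge)
  w[u < 0 | u > 1] <- 0
  m <- 0.75 + 0.25 * (0.5 - 0.5 * cos(4 * pi * pmin(pmax(u, 0), 1)))
  w * m
}

# 1/f^a noise with unit variance via spectral shaping; the amplitude scale
# is symmetric in bin frequency so the shaped spectrum stays Hermitian
pink_noise <- function(n, exponent = 1) {
  if (n < 2L) return(rnorm(n))
  nfft <- 2L^ceiling(log2(n))
  white <- rnorm(nfft)
  spec <- fft(white)
  bins <- 0:(nfft - 1)
  fbin <- pmin(bins, nfft - bins)  # alias frequency of each bin
  scale <- ifelse(fbin == 0, 0, fbin^(-exponent / 2))
  x <- Re(fft(spec * scale, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Simulate a complete synthetic split-belt session
#'
#' Generates the raw multirate signals of one subject walking the given
#' schedule: per-belt vertical ground-reaction forces (two-hump stance
#' waveform gated by the true gait events), ankle-marker anterior-posterior
#' positions (carried backwards by the belt during stance, swung forward to
#' land so that the step lengths at foot contact reproduce the true SLA
#' exactly), and per-region source signals (1/f^a background plus
#' gait-phase-locked Hann-windowed oscillatory bursts whose amplitude grows
#' with the stride's |SLA|). Ground truth (event times, SLA, asymmetric
#' flags, injected effect windows) is returned alongside.
#'
#' @param schedule A `belt_schedule`.
#' @param cfg A `synthetic_config`.
#' @param subject_id Label stored in the session.
#' @param signals Character vector among `"grf"`, `"markers"`, `"sources"`;
#'   restrict to the streams a test actually needs to keep generation cheap.
#' @return A `gait_session`: list with `schedule`, `config`, `subject_id`,
#'   tibbles `grf` (time, left, right), `markers` (time, left_ap, right_ap),
#'   `sources` (time + one column per region), and `truth` (a list with
#'   `strides`, `flags`, `effect_windows`).
#' @export
simulate_session <- function(schedule, cfg, subject_id = "s01",
                             signals = c("grf", "markers", "sources")) {
  set.seed(cfg$seed)
  simulate_session_impl(schedule, cfg, subject_id, signals)
}

simulate_session_impl <- function(schedule, cfg, subject_id, signals) {
  strides <- simulate_strides(schedule, cfg)
  total <- protocol_duration(schedule)
  out <- list(schedule = schedule, config = cfg, subject_id = subject_id)

  if ("grf" %in% signals) {
    fs <- attr(schedule, "sample_rate_grf")
    t <- seq(0, total, by = 1 / fs)
    out$grf <- tibble::tibble(
      time = t,
      left = grf_waveform(t, stance_intervals(strides, "left"),
                          cfg$grf_peak_force),
      right = grf_waveform(t, stance_intervals(strides, "right"),
                           cfg$grf_peak_force)
    )
  }
  if ("markers" %in% signals) {
    out$markers <- simulate_markers(schedule, strides, cfg)
  }
  if ("sources" %in% signals) {
    out$sources <- simulate_sources(schedule, strides, cfg)
  }

  flags <- truth_asymmetric_flags(strides, schedule)
  out$truth <- list(
    strides = strides,
    flags = flags,
    effect_windows = truth_effect_windows(cfg)
  )
  structure(out, class = "gait_session")
}

# stance intervals (start, end) for one foot across all strides; the left
# foot's stance spans mid-cycle of one stride to early next stride
stance_intervals <- function(strides, foot = c("left", "right")) {
  foot <- match.arg(foot)
  if (foot == "right") {
    tibble::tibble(start = strides$rfc_s, end = strides$rfo_s)
  } else {
    n <- nrow(strides)
    # the session opens mid-way through a left stance: back-date its onset
    # so the force waveform at t = 0 is already loaded
    stance_frac <- event_phase_fractions[["rfo"]]
    tibble::tibble(
      start = c(strides$lfo_s[1] - stance_frac * strides$cycle_s[1],
                strides$lfc_s),
      end = c(strides$lfo_s, strides$stride_end_s[n] +
                event_phase_fractions[["lfo"]] * strides$cycle_s[n])
    )
  }
}

# index range of a uniform grid t = t0 + (0:n-1)/fs covered by [a, b]
grid_window <- function(a, b, t0, fs, n) {
  i0 <- max(1L, as.integer(ceiling((a - t0) * fs - 1e-9)) + 1L)
  i1 <- min(n, as.integer(floor((b - t0) * fs + 1e-9)) + 1L)
  if (i0 > i1) integer() else i0:i1
}

grf_waveform <- function(t, intervals, peak) {
  f <- numeric(length(t))
  fs <- 1 / (t[2] - t[1])
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]
    b <- intervals$end[i]
    idx <- grid_window(a, b, t[1], fs, length(t))
    if (length(idx)) {
      f[idx] <- f[idx] + peak * stance_template((t[idx] - a) / (b - a))
    }
  }
  f
}

# Ankle-marker anterior-posterior trajectories. During stance the marker is
# carried backwards at the commanded belt speed; during swing it follows a
# smooth raised-cosine path to the landing position chosen so that the
# anterior-posterior marker separation at each foot contact equals the
# stride's target step length (fast at RFC, slow at LFC).
simulate_markers <- function(schedule, strides, cfg) {
  fm <- attr(schedule, "sample_rate_markers")
  total <- protocol_duration(schedule)
  t <- seq(0, total, by = 1 / fm)
  speeds <- belt_speed_at(schedule, t)
  # belt displacement integrals, evaluated at arbitrary times
  disp_l <- cumtrapz(t, speeds$left)
  disp_r <- cumtrapz(t, speeds$right)
  # fast linear interpolation on the uniform marker grid
  grid_lerp <- function(y) {
    nmax <- length(y)
    function(tt) {
      u <- pmin(pmax(tt * fm, 0), nmax - 1)
      i <- pmin(floor(u), nmax - 2)
      f <- u - i
      (1 - f) * y[i + 1] + f * y[i + 2]
    }
  }
  D_l <- grid_lerp(disp_l)
  D_r <- grid_lerp(disp_r)

  n <- nrow(strides)
  S <- cfg$step_length_sum
  fast_len <- S * (1 + strides$sla) / 2
  slow_len <- S * (1 - strides$sla) / 2

  # landing positions: R_k for the right foot at rfc_k, L_k for the left
  # foot at lfc_k; left foot starts in stance at position 0 at time 0
  R <- numeric(n)
  L <- numeric(n)
  ap_l_at_rfc <- numeric(n)
  ap_r_at_lfc <- numeric(n)
  for (k in seq_len(n)) {
    ap_l_at_rfc[k] <- if (k == 1L) {
      0 - (D_l(strides$rfc_s[1]) - D_l(0))
    } else {
      L[k - 1L] - (D_l(strides$rfc_s[k]) - D_l(strides$lfc_s[k - 1L]))
    }
    R[k] <- ap_l_at_rfc[k] + fast_len[k]
    ap_r_at_lfc[k] <- R[k] - (D_r(strides$lfc_s[k]) - D_r(strides$rfc_s[k]))
    L[k] <- ap_r_at_lfc[k] + slow_len[k]
  }

  # C1 swing: cubic Hermite from (ta, p0) to (tb, p1) whose end velocities
  # match the belt-carried stance velocity, so marker trajectories have no
  # velocity kink at foot contact or lift-off. Anchor speeds are looked up
  # for all strides at once.
  fm_n <- length(t)
  anchor_t <- c(strides$rfo_s, strides$rfc_s, strides$lfo_s, strides$lfc_s,
                total)
  anchor_sp <- belt_speed_at(schedule, anchor_t)
  speed_at <- function(tt, side) {
    anchor_sp[[side]][match(tt, anchor_t)]
  }
  hermite <- function(tt, ta, tb, p0, p1, v0, v1) {
    dt <- tb - ta
    u <- (tt - ta) / dt
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    h00 * p0 + h10 * dt * v0 + h01 * p1 + h11 * dt * v1
  }

  # right marker: stance [rfc_k, rfo_k], swing [rfo_k, rfc_{k+1}]
  ap_r <- rep(NA_real_, fm_n)
  for (k in seq_len(n)) {
    in_st <- grid_window(strides$rfc_s[k], strides$rfo_s[k], t[1], fm, fm_n)
    ap_r[in_st] <- R[k] - (D_r(t[in_st]) - D_r(strides$rfc_s[k]))
    t_next <- if (k < n) strides$rfc_s[k + 1L] else total
    target <- if (k < n) R[k + 1L] else R[k]
    in_sw <- grid_window(strides$rfo_s[k], t_next, t[1], fm, fm_n)
    in_sw <- in_sw[t[in_sw] > strides$rfo_s[k] & t[in_sw] < t_next]
    if (length(in_sw)) {
      p0 <- R[k] - (D_r(strides$rfo_s[k]) - D_r(strides$rfc_s[k]))
      ap_r[in_sw] <- hermite(t[in_sw], strides$rfo_s[k], t_next, p0, target,
                             -speed_at(strides$rfo_s[k], "right"),
                             -speed_at(t_next, "right"))
    }
  }
  pre <- t < strides$rfc_s[1]   # before the first stride: hold on belt
  ap_r[pre] <- R[1] - (D_r(t[pre]) - D_r(strides$rfc_s[1]))
  ap_r[is.na(ap_r)] <- R[n] - (D_r(t[is.na(ap_r)]) - D_r(strides$rfc_s[n]))

  # left marker: initial stance [0, lfo_1], swing [lfo_k, lfc_k],
  # stance [lfc_k, lfo_{k+1}]
  ap_l <- rep(NA_real_, fm_n)
  in0 <- grid_window(0, strides$lfo_s[1], t[1], fm, fm_n)
  ap_l[in0] <- 0 - (D_l(t[in0]) - D_l(0))
  for (k in seq_len(n)) {
    in_sw <- grid_window(strides$lfo_s[k], strides$lfc_s[k], t[1], fm, fm_n)
    in_sw <- in_sw[t[in_sw] > strides$lfo_s[k] & t[in_sw] < strides$lfc_s[k]]
    if (length(in_sw)) {
      p0 <- if (k == 1L) {
        0 - (D_l(strides$lfo_s[1]) - D_l(0))
      } else {
        L[k - 1L] - (D_l(strides$lfo_s[k]) - D_l(strides$lfc_s[k - 1L]))
      }
      ap_l[in_sw] <- hermite(t[in_sw], strides$lfo_s[k], strides$lfc_s[k],
                             p0, L[k],
                             -speed_at(strides$lfo_s[k], "left"),
                             -speed_at(strides$lfc_s[k], "left"))
    }
    end_st <- if (k < n) strides$lfo_s[k + 1L] else total
    in_st <- grid_window(strides$lfc_s[k], end_st, t[1], fm, fm_n)
    ap_l[in_st] <- L[k] - (D_l(t[in_st]) - D_l(strides$lfc_s[k]))
  }
  ap_l[is.na(ap_l)] <- L[n] - (D_l(t[is.na(ap_l)]) - D_l(strides$lfc_s[n]))

  tibble::tibble(time = t, left_ap = ap_l, right_ap = ap_r)
}

simulate_sources <- function(schedule, strides, cfg) {
  fs <- attr(schedule, "sample_rate_sources")
  total <- protocol_duration(schedule)
  t <- seq(0, total, by = 1 / fs)
  out <- tibble::tibble(time = t)
  spec <- cfg$burst_spec
  for (i in seq_len(nrow(spec))) {
    x <- cfg$source_noise_sd * pink_noise(length(t), cfg$pink_noise_exponent)
    f0 <- (spec$band_lo[i] + spec$band_hi[i]) / 2
    centers <- strides$rfc_s + spec$gait_phase_center[i] / 100 * strides$cycle_s
    widths <- spec$phase_width[i] / 100 * strides$cycle_s
    amps <- spec$baseline_amplitude[i] +
      spec$gain_vs_error[i] * abs(strides$sla)
    phases <- runif(nrow(strides), 0, 2 * pi)
    for (k in seq_len(nrow(strides))) {
      a <- centers[k] - widths[k] / 2
      b <- centers[k] + widths[k] / 2
      idx <- grid_window(a, b, t[1], fs, length(t))
      if (length(idx)) {
        u <- (t[idx] - a) / (b - a)
        hann <- 0.5 - 0.5 * cos(2 * pi * u)
        x[idx] <- x[idx] +
          amps[k] * hann * sin(2 * pi * f0 * (t[idx] - centers[k]) + phases[k])
      }
    }
    out[[spec$region[i]]] <- x
  }
  out
}

# ground-truth asymmetric flags: the 2-SD criterion applied to the
# noiseless reference statistics (last 30 strides before the ramp)
truth_asymmetric_flags <- function(strides, schedule) {
  pt <- phase_times(schedule)
  ramp_start <- pt$start_s[match("ramp", pt$phase)]
  if (is.na(ramp_start)) return(rep(FALSE, nrow(strides)))
  ref_idx <- which(strides$stride_end_s <= ramp_start)
  ref_idx <- tail(ref_idx, 30)
  if (length(ref_idx) < 30) return(rep(FALSE, nrow(strides)))
  crit <- asymmetry_criterion(strides$sla[ref_idx], k = 2)
  detect_asymmetric_strides(strides$sla, crit)
}

truth_effect_windows <- function(cfg) {
  spec <- cfg$burst_spec
  tibble::tibble(
    region = spec$region,
    band_lo = spec$band_lo,
    band_hi = spec$band_hi,
    phase_lo = spec$gait_phase_center - spec$phase_width / 2,
    phase_hi = spec$gait_phase_center + spec$phase_width / 2,
    gain_vs_error = spec$gain_vs_error,
    baseline_amplitude = spec$baseline_amplitude
  )
}

#' Simulate a cohort of synthetic sessions
#'
#' One master seed spawns an independent per-subject stream: subject-level
#' seeds are drawn once from the master stream, then each session is
#' generated under its own seed, so adding subjects never perturbs the
#' sessions of earlier ones.
#'
#' @inheritParams simulate_session
#' @return List of `gait_session` objects of length `cfg$n_subjects`.
#' @export
simulate_cohort <- function(schedule, cfg,
                            signals = c("grf", "markers", "sources")) {
  set.seed(cfg$seed)
  subject_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)
  purrr::map(seq_len(cfg$n_subjects), function(i) {
    set.seed(subject_seeds[i])
    simulate_session_impl(schedule, cfg,
                          subject_id = sprintf("s%02d", i), signals)
  })
}
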