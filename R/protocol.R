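#' Build the split-belt session schedule
#'
#' Constructs the full belt-speed program of a split-belt adaptation session:
#' three tied-belt familiarisation blocks (slow 0.6, fast 1.2, medium
#' 0.9 m/s), a 15-min abrupt 2:1 split introduced at 0.2 m/s^2, a 10-min
#' tied post block, a 5-min gradual ramp in which the right belt rises
#' 0.9 to 1.2 m/s while the left belt falls 0.9 to 0.6 m/s (0.001 m/s^2 on
#' each belt), a 2-min 2:1 hold, and a final 5-min tied post block. Belt
#' speed is piecewise linear in time, so every abrupt transition is a short
#' ramp at `transition_accel` and the profile is continuous.
#'
#' @param pre_block_s Duration of each tied familiarisation block (s).
#' @param abrupt_split_s Duration of the abrupt 2:1 hold (s).
#' @param post1_s Duration of the first tied post-adaptation block (s).
#' @param ramp_s Duration of the gradual ramp (s); with the default speeds
#'   this yields a belt acceleration of 0.001 m/s^2.
#' @param split_hold_s Duration of the 2:1 hold that ends the gradual
#'   perturbation (s).
#' @param post2_s Duration of the second tied post-adaptation block (s).
#' @param tied_speed Tied-belt reference speed (m/s).
#' @param fast_speed,slow_speed Terminal fast/slow belt speeds (m/s); their
#'   ratio is the terminal split ratio (2:1 by default).
#' @param transition_accel Belt acceleration used for abrupt speed changes
#'   (m/s^2).
#' @param sample_rate_grf,sample_rate_markers,sample_rate_sources Sampling
#'   rates (Hz) that a simulated session generated from this schedule uses
#'   for the force plates, the ankle markers and the source-level neural
#'   series.
#'
#' @return A `belt_schedule`: a tibble with one row per phase and columns
#'   `phase`, `duration_s`, `left_start`, `left_end`, `right_start`,
#'   `right_end`, plus sampling-rate attributes.
#' @export
#' @examples
#' sched <- split_belt_protocol()
#' # ramp acceleration on each belt, from speeds and duration
#' ramp <- sched[sched$phase == "ramp", ]
#' abs(ramp$right_end - ramp$right_start) / ramp$duration_s
split_belt_protocol <- function(pre_block_s = 180,
                                abrupt_split_s = 900,
                                post1_s = 600,
                                ramp_s = 300,
                                split_hold_s = 120,
                                post2_s = 300,
                                tied_speed = 0.9,
                                fast_speed = 1.2,
                                slow_speed = 0.6,
                                transition_accel = 0.2,
                                sample_rate_grf = 1000,
                                sample_rate_markers = 100,
                                sample_rate_sources = 512) {
  stopifnot(tied_speed > 0, fast_speed > 0, slow_speed >= 0,
            transition_accel > 0)
  trans <- function(name, l0, l1, r0, r1) {
    dur <- max(abs(l1 - l0), abs(r1 - r0)) / transition_accel
    tibble::tibble(phase = name, duration_s = dur,
                   left_start = l0, left_end = l1,
                   right_start = r0, right_end = r1)
  }
  hold <- function(name, dur, l, r) {
    tibble::tibble(phase = name, duration_s = dur,
                   left_start = l, left_end = l,
                   right_start = r, right_end = r)
  }
  phases <- dplyr::bind_rows(
    hold("pre_slow", pre_block_s, slow_speed, slow_speed),
    trans("pre_fast_onset", slow_speed, fast_speed, slow_speed, fast_speed),
    hold("pre_fast", pre_block_s, fast_speed, fast_speed),
    trans("pre_medium_onset", fast_speed, tied_speed, fast_speed, tied_speed),
    hold("pre_medium", pre_block_s, tied_speed, tied_speed),
    trans("abrupt_onset", tied_speed, slow_speed, tied_speed, fast_speed),
    hold("abrupt_split", abrupt_split_s, slow_speed, fast_speed),
    trans("post1_onset", slow_speed, tied_speed, fast_speed, tied_speed),
    hold("post1", post1_s, tied_speed, tied_speed),
    tibble::tibble(phase = "ramp", duration_s = ramp_s,
                   left_start = tied_speed, left_end = slow_speed,
                   right_start = tied_speed, right_end = fast_speed),
    hold("split_hold", split_hold_s, slow_speed, fast_speed),
    trans("post2_onset", slow_speed, tied_speed, fast_speed, tied_speed),
    hold("post2", post2_s, tied_speed, tied_speed)
  )
  new_belt_schedule(phases,
                    sample_rate_grf = sample_rate_grf,
                    sample_rate_markers = sample_rate_markers,
                    sample_rate_sources = sample_rate_sources)
}

#' Create a belt schedule from a phase table
#'
#' Lower-level constructor used by [split_belt_protocol()] and by tests that
#' need shortened schedules. Validates the phase table: positive durations,
#' non-negative speeds, and continuity of the speed profile across phase
#' boundaries.
#'
#' @param phases Data frame with columns `phase`, `duration_s`,
#'   `left_start`, `left_end`, `right_start`, `right_end`.
#' @param sample_rate_grf,sample_rate_markers,sample_rate_sources Sampling
#'   rates in Hz.
#' @return A `belt_schedule` tibble.
#' @export
new_belt_schedule <- function(phases,
                              sample_rate_grf = 1000,
                              sample_rate_markers = 100,
                              sample_rate_sources = 512) {
  req <- c("phase", "duration_s", "left_start", "left_end",
           "right_start", "right_end")
  missing_cols <- setdiff(req, names(phases))
  if (length(missing_cols)) {
    abort(paste0("schedule phases missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  phases <- tibble::as_tibble(phases)[req]
  if (any(phases$duration_s <= 0)) abort("phase durations must be > 0")
  speeds <- unlist(phases[c("left_start", "left_end",
                            "right_start", "right_end")])
  if (any(speeds < 0)) abort("belt speeds must be >= 0")
  n <- nrow(phases)
  if (n > 1L) {
    jump_l <- abs(phases$left_start[-1] - phases$left_end[-n])
    jump_r <- abs(phases$right_start[-1] - phases$right_end[-n])
    if (any(jump_l > 1e-9) || any(jump_r > 1e-9)) {
      abort("belt speed profile must be continuous across phase boundaries")
    }
  }
  structure(phases,
            class = c("belt_schedule", class(tibble::tibble())),
            sample_rate_grf = sample_rate_grf,
            sample_rate_markers = sample_rate_markers,
            sample_rate_sources = sample_rate_sources)
}

#' Phase start and end times of a schedule
#'
#' @param schedule A `belt_schedule`.
#' @return Tibble with `phase`, `start_s`, `end_s`.
#' @export
phase_times <- function(schedule) {
  end <- cumsum(schedule$duration_s)
  tibble::tibble(phase = schedule$phase,
                 start_s = c(0, head(end, -1)),
                 end_s = end)
}

#' Total scheduled session duration in seconds
#' @param schedule A `belt_schedule`.
#' @export
protocol_duration <- function(schedule) sum(schedule$duration_s)

#' Commanded belt speeds at given times
#'
#' Evaluates the piecewise-linear belt-speed program. Times beyond the end
#' of the session hold the terminal speeds; negative times hold the initial
#' speeds.
#'
#' @param schedule A `belt_schedule`.
#' @param time Numeric vector of times (s).
#' @return Tibble with columns `time`, `left`, `right` (m/s).
#' @export
belt_speed_at <- function(schedule, time) {
  pt <- phase_times(schedule)
  idx <- pmin(pmax(findInterval(pmax(time, 0), pt$start_s), 1L), nrow(pt))
  frac <- (pmax(pmin(time, pt$end_s[nrow(pt)]), 0) - pt$start_s[idx]) /
    schedule$duration_s[idx]
  frac <- pmin(pmax(frac, 0), 1)
  tibble::tibble(
    time = time,
    left = schedule$left_start[idx] +
      frac * (schedule$left_end[idx] - schedule$left_start[idx]),
    right = schedule$right_start[idx] +
      frac * (schedule$right_end[idx] - schedule$right_start[idx])
  )
}
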