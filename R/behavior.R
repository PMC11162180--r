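#' Step length asymmetry
#'
#' Normalized difference of the fast- and slow-leading step lengths,
#' `(fast - slow) / (fast + slow)`. Positive values mean the fast-leading
#' step was longer. Returns `NA` where the denominator is not positive.
#'
#' @param fast,slow Step lengths (m); vectorized.
#' @return Unitless asymmetry in (-1, 1) for positive step lengths.
#' @export
#' @examples
#' compute_sla(0.6, 0.4)  # 0.2
compute_sla <- function(fast, slow) {
  s <- fast + slow
  ifelse(is.na(s) | s <= 0, NA_real_, (fast - slow) / s)
}

#' Belt symmetry
#'
#' Normalized difference of the fast and slow belt speeds, computed exactly
#' like step length asymmetry: `(fast - slow) / (fast + slow)`.
#'
#' @param fast,slow Belt speeds (m/s); vectorized.
#' @return Unitless symmetry in `[-1, 1]` for non-negative speeds.
#' @export
#' @examples
#' compute_belt_symmetry(1.2, 0.6)  # 1/3
compute_belt_symmetry <- function(fast, slow) {
  s <- fast + slow
  ifelse(is.na(s) | s <= 0, NA_real_, (fast - slow) / s)
}

#' Step lengths at foot contact from ankle markers
#'
#' At each foot contact the step length is the absolute anterior-posterior
#' distance between the two ankle markers: the fast step length is measured
#' at right foot contact (the right belt is the fast belt), the slow step
#' length at left foot contact. Marker positions are linearly interpolated
#' at the event times; events outside the marker time range leave the
#' stride's value missing.
#'
#' @param markers Tibble with columns `time`, `left_ap`, `right_ap` (m).
#' @param events Gait-event tibble (see [detect_gait_events()]).
#' @return `events` with columns `step_length_fast`, `step_length_slow` (m)
#'   appended.
#' @export
compute_step_lengths <- function(markers, events) {
  stopifnot(all(c("time", "left_ap", "right_ap") %in% names(markers)))
  l_at <- function(tt) interp_at(markers$time, markers$left_ap, tt)
  r_at <- function(tt) interp_at(markers$time, markers$right_ap, tt)
  events$step_length_fast <- abs(r_at(events$rfc_s) - l_at(events$rfc_s))
  events$step_length_slow <- abs(l_at(events$lfc_s) - r_at(events$lfc_s))
  events
}

#' Normalize a step length asymmetry series to a baseline window
#'
#' Subtracts the subject's mean asymmetry over the baseline strides
#' (typically the tied-belt block preceding abrupt adaptation) so behaviour
#' is comparable across subjects.
#'
#' @param sla Numeric SLA series.
#' @param baseline_strides Integer indices into `sla` defining the baseline
#'   window.
#' @return Numeric series, `sla` minus its baseline mean.
#' @export
normalize_sla <- function(sla, baseline_strides) {
  baseline_strides <- baseline_strides[!is.na(baseline_strides)]
  if (!length(baseline_strides)) abort("baseline window is empty")
  if (any(baseline_strides < 1 | baseline_strides > length(sla))) {
    abort("baseline indices out of range")
  }
  sla - mean(sla[baseline_strides], na.rm = TRUE)
}

#' Estimate belt speeds from ankle-marker velocity during stance
#'
#' Each belt's speed on a stride is the mean absolute anterior-posterior
#' velocity of the ipsilateral ankle marker over that foot's stance
#' interval (the foot is carried by the belt while on it). The right foot's
#' stance runs RFC to RFO of the stride; the left foot's stance runs LFC of
#' the stride to LFO of the following stride (or the stride end for the
#' final stride). Stance intervals covering fewer than 3 marker samples
#' yield a missing value.
#'
#' @param markers Tibble with `time`, `left_ap`, `right_ap`.
#' @param events Gait-event tibble.
#' @return `events` with `belt_speed_fast` (right belt) and
#'   `belt_speed_slow` (left belt) in m/s appended.
#' @export
estimate_belt_speeds <- function(markers, events) {
  tt <- markers$time
  vel <- function(x) c(NA, diff(x) / diff(tt))
  v_l <- vel(markers$left_ap)
  v_r <- vel(markers$right_ap)
  mean_speed <- function(v, a, b) {
    i0 <- findInterval(a - 1e-12, tt) + 1L
    i1 <- findInterval(b + 1e-12, tt)
    if (is.na(a) || is.na(b) || i1 - i0 + 1L < 3L) return(NA_real_)
    mean(abs(v[i0:i1]), na.rm = TRUE)
  }
  n <- nrow(events)
  fast <- slow <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    fast[k] <- mean_speed(v_r, events$rfc_s[k], events$rfo_s[k])
    left_end <- if (k < n) events$lfo_s[k + 1L] else events$stride_end_s[k]
    slow[k] <- mean_speed(v_l, events$lfc_s[k], left_end)
  }
  events$belt_speed_fast <- fast
  events$belt_speed_slow <- slow
  events
}

#' Clean a per-stride belt-speed series
#'
#' Three steps, in order: (i) missing values are linearly interpolated
#' (edges held at the nearest observed value); (ii) a 6-tap moving-average
#' FIR filter (each coefficient 1/6) is applied, with shorter windows at the
#' series start so constant series pass through unchanged; (iii) elements
#' deviating more than 3 local standard deviations from the local mean of a
#' 6-element sliding window are replaced by the mean of the nearest valid
#' neighbouring strides.
#'
#' @param x Numeric series (m/s), length >= 6.
#' @param k_outlier Local SD multiplier for outlier detection.
#' @return Cleaned numeric series of the same length.
#' @export
condition_belt_series <- function(x, k_outlier = 3) {
  n <- length(x)
  if (n < 6L) abort("belt-speed series must have at least 6 elements")
  if (all(is.na(x))) abort("belt-speed series is entirely missing")
  # (i) linear interpolation of missing values
  if (anyNA(x)) {
    obs <- which(!is.na(x))
    x <- stats::approx(obs, x[obs], xout = seq_len(n), rule = 2)$y
  }
  # (ii) causal 6-tap moving average; partial windows at the start
  csum <- cumsum(x)
  smoothed <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - 5L)
    smoothed[i] <- (csum[i] - if (j > 1L) csum[j - 1L] else 0) / (i - j + 1L)
  }
  # (iii) replace local outliers (6-element centred window: 3 back, 2 ahead)
  is_out <- logical(n)
  for (i in seq_len(n)) {
    j0 <- max(1L, i - 3L)
    j1 <- min(n, i + 2L)
    w <- smoothed[j0:j1]
    mu <- mean(w)
    s <- sd(w)
    if (is.finite(s) && s > 0 && abs(smoothed[i] - mu) > k_outlier * s) {
      is_out[i] <- TRUE
    }
  }
  out <- smoothed
  for (i in which(is_out)) {
    prev <- i - 1L
    while (prev >= 1L && is_out[prev]) prev <- prev - 1L
    nxt <- i + 1L
    while (nxt <= n && is_out[nxt]) nxt <- nxt + 1L
    neigh <- c(if (prev >= 1L) smoothed[prev], if (nxt <= n) smoothed[nxt])
    if (length(neigh)) out[i] <- mean(neigh)
  }
  out
}

#' Asymmetric-stride criterion from a reference window
#'
#' Builds the detection criterion from the last 30 strides of the reference
#' condition: a stride is asymmetric when its |SLA| exceeds the reference
#' mean plus `k` reference standard deviations.
#'
#' @param reference_sla SLA values of the reference condition; at least 30
#'   are required and only the last 30 are used.
#' @param k SD multiplier (2 by default).
#' @return An `asym_criterion` list with `mu`, `sigma`, `k`, `n_reference`.
#' @export
asymmetry_criterion <- function(reference_sla, k = 2) {
  reference_sla <- reference_sla[!is.na(reference_sla)]
  if (length(reference_sla) < 30L) {
    abort("reference window must contain at least 30 strides")
  }
  win <- tail(reference_sla, 30)
  structure(list(mu = mean(win), sigma = sd(win), k = k,
                 n_reference = 30L),
            class = "asym_criterion")
}

#' Flag asymmetric strides
#'
#' @param sla Numeric SLA series.
#' @param criterion An `asym_criterion` from [asymmetry_criterion()].
#' @return Logical vector: `|sla| > mu + k * sigma` (`NA` SLA gives `FALSE`).
#' @export
detect_asymmetric_strides <- function(sla, criterion) {
  stopifnot(inherits(criterion, "asym_criterion"))
  flag <- abs(sla) > criterion$mu + criterion$k * criterion$sigma
  flag[is.na(flag)] <- FALSE
  flag
}

#' Median split of asymmetric strides into large and small errors
#'
#' Asymmetric strides with |SLA| strictly above the median |SLA| of the
#' asymmetric strides are classed `large`; those at or below the median are
#' `small`. Non-asymmetric strides are `none`. With fewer than two
#' asymmetric strides every stride is `none` and a warning is raised.
#'
#' @param sla Numeric SLA series.
#' @param is_asymmetric Logical flags, same length as `sla`.
#' @return Factor with levels `none`, `small`, `large`.
#' @export
median_split_errors <- function(sla, is_asymmetric) {
  stopifnot(length(sla) == length(is_asymmetric))
  cls <- rep("none", length(sla))
  idx <- which(is_asymmetric & !is.na(sla))
  if (length(idx) < 2L) {
    warn("fewer than 2 asymmetric strides; no error-size classes assigned")
  } else {
    med <- stats::median(abs(sla[idx]))
    cls[idx] <- ifelse(abs(sla[idx]) > med, "large", "small")
  }
  factor(cls, levels = c("none", "small", "large"))
}

#' Strides to steady state
#'
#' Steady state is the mean SLA over the last `window` strides of the
#' adaptation phase; its band is that mean plus or minus `k` standard
#' deviations computed over the same window. The function returns the index
#' of the first stride that starts a run of at least `run_length`
#' consecutive strides inside the band, or `NA` if no such run exists.
#'
#' @param sla SLA series of one adaptation phase (length >= 40).
#' @param window Width of the terminal window defining steady state.
#' @param run_length Required number of consecutive in-band strides.
#' @param k SD multiplier for the band half-width.
#' @return Integer stride index, or `NA_integer_`.
#' @export
detect_steady_state <- function(sla, window = 30, run_length = 10, k = 2) {
  n <- length(sla)
  if (n < window + run_length) {
    abort(sprintf("phase too short: %d strides, need at least %d",
                  n, window + run_length))
  }
  ref <- tail(sla, window)
  mu <- mean(ref, na.rm = TRUE)
  s <- sd(ref, na.rm = TRUE)
  inband <- abs(sla - mu) <= k * s
  inband[is.na(inband)] <- FALSE
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (inband[i]) run + 1L else 0L
    if (run == run_length) return(as.integer(i - run_length + 1))
  }
  NA_integer_
}

#' Percentage of asymmetric strides
#'
#' @param is_asymmetric Logical flags.
#' @return Percentage in `[0, 100]`.
#' @export
pct_asymmetric <- function(is_asymmetric) {
  100 * mean(is_asymmetric, na.rm = TRUE)
}

#' Cohort adaptation-performance scores and their association
#'
#' Abrupt performance is the number of strides to steady state; gradual
#' performance is the percentage of asymmetric strides. Each raw metric is
#' min-max normalized across the cohort to `[0, 1]` and inverted
#' (`1 - normalized`), so 1 is always the better adapter. An ordinary
#' least-squares regression of the abrupt score on the gradual score
#' quantifies their association.
#'
#' @param perf Tibble with one row per subject and columns `subject`,
#'   `strides_to_steady_state`, `pct_asymmetric`.
#' @return A `performance_summary`: list with `scores` (tibble adding
#'   `abrupt_score`, `gradual_score`) and `fit` (the `lm` object). Use
#'   [glance()] for slope, adjusted R-squared and p-value.
#' @export
performance_metrics <- function(perf) {
  req <- c("subject", "strides_to_steady_state", "pct_asymmetric")
  missing_cols <- setdiff(req, names(perf))
  if (length(missing_cols)) {
    abort(paste0("performance table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(perf) < 2L) {
    abort("cohort must contain at least 2 subjects for min-max normalization")
  }
  minmax_inv <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0.5, length(x)))
    1 - (x - rng[1]) / diff(rng)
  }
  scores <- tibble::as_tibble(perf)
  scores$abrupt_score <- minmax_inv(scores$strides_to_steady_state)
  scores$gradual_score <- minmax_inv(scores$pct_asymmetric)
  fit <- lm(abrupt_score ~ gradual_score, data = scores)
  structure(list(scores = scores, fit = fit),
            class = "performance_summary")
}
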