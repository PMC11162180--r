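#' Low-pass filter and resample ground-reaction forces
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth low-pass
#' filter to every force channel and regrids the result onto a uniform
#' `target_rate` grid. Edge transients of the forward-backward pass are
#' suppressed by odd-symmetric reflection padding, so the DC level is
#' preserved; regridding uses cubic-spline interpolation, which is
#' delay-free and essentially exact for a signal already band-limited far
#' below both Nyquist rates.
#'
#' @param grf Data frame with a `time` column (s) and one numeric column per
#'   force channel (N).
#' @param cutoff Low-pass cutoff frequency (Hz); must be below the native
#'   Nyquist frequency.
#' @param target_rate Output sampling rate (Hz); `NULL` keeps the native
#'   rate.
#' @return Tibble with the resampled `time` grid and filtered channels.
#' @export
filter_grf <- function(grf, cutoff = 6, target_rate = 512) {
  stopifnot("time" %in% names(grf))
  native <- infer_rate(grf$time)
  if (cutoff >= native / 2) {
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  cutoff, native / 2))
  }
  bf <- signal::butter(2, cutoff / (native / 2), type = "low")
  pad <- min(ceiling(5 * native / cutoff), length(grf$time) - 1L)
  chans <- setdiff(names(grf), "time")
  filtered <- purrr::map(grf[chans], function(x) {
    n <- length(x)
    xp <- c(2 * x[1] - x[1 + rev(seq_len(pad))],
            x,
            2 * x[n] - x[n - seq_len(pad)])
    y <- signal::filtfilt(bf, xp)
    y[pad + seq_len(n)]
  })
  if (is.null(target_rate) || abs(target_rate - native) < 1e-9) {
    out <- tibble::tibble(time = grf$time)
    out[chans] <- filtered
    return(out)
  }
  n_out <- floor((length(grf$time) - 1) * target_rate / native) + 1
  new_time <- grf$time[1] + (seq_len(n_out) - 1) / target_rate
  out <- tibble::tibble(time = new_time)
  out[chans] <- purrr::map(filtered, function(x) {
    stats::spline(grf$time, x, xout = new_time, method = "fmm")$y
  })
  out
}

# Threshold crossings of one force channel with per-foot debounce. The
# crossings of a continuous signal alternate (up, down, up, ...); a
# crossing closer than min_phase to the previously kept one delimits a
# spurious short phase (threshold chatter or a force dropout), and both
# crossings of that phase are cancelled. Returns tibble(time, type) with
# type in contact/off, alternating with gaps >= min_phase.
foot_crossings <- function(time, force, threshold, min_phase) {
  above <- force >= threshold
  n <- length(above)
  if (n < 2L) return(tibble::tibble(time = numeric(), type = character()))
  up <- which(!above[-n] & above[-1]) + 1L
  down <- which(above[-n] & !above[-1]) + 1L
  ev <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(idx = up, type = "contact"),
    tibble::tibble(idx = down, type = "off")
  ), .data$idx)
  if (!nrow(ev)) return(tibble::tibble(time = numeric(), type = character()))
  stack <- integer(0)
  for (i in seq_len(nrow(ev))) {
    if (length(stack) &&
        time[ev$idx[i]] - time[ev$idx[stack[length(stack)]]] < min_phase) {
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, i)
    }
  }
  tibble::tibble(time = time[ev$idx[stack]], type = ev$type[stack])
}

#' Detect gait events from filtered ground-reaction forces
#'
#' Foot contact is the upward crossing of the force threshold, foot-off the
#' downward crossing. A crossing closer than `min_phase` to the previously
#' kept crossing on the same foot delimits a spurious short force phase,
#' and both of its crossings are cancelled (debounce against threshold
#' chatter and brief dropouts). Events are then interleaved into strides beginning at right
#' foot contact (RFC); a stride is kept only if exactly the sequence
#' RFC < LFO < LFC < RFO < next RFC occurs, otherwise it is dropped with a
#' message.
#'
#' @param grf Filtered force table with columns `time`, `left`, `right` (N).
#' @param threshold Contact threshold (N).
#' @param min_phase Debounce interval (s).
#' @return A gait-event tibble with columns `stride_index`, `rfc_s`,
#'   `lfo_s`, `lfc_s`, `rfo_s`, `stride_end_s` (the next RFC) and
#'   `abnormal` (initialised `FALSE`; see [flag_abnormal_latencies()]).
#' @export
detect_gait_events <- function(grf, threshold = 10, min_phase = 0.1) {
  stopifnot(all(c("time", "left", "right") %in% names(grf)))
  right <- foot_crossings(grf$time, grf$right, threshold, min_phase)
  left <- foot_crossings(grf$time, grf$left, threshold, min_phase)

  empty <- tibble::tibble(
    stride_index = integer(), rfc_s = numeric(), lfo_s = numeric(),
    lfc_s = numeric(), rfo_s = numeric(), stride_end_s = numeric(),
    abnormal = logical()
  )
  rfc <- right$time[right$type == "contact"]
  rfo <- right$time[right$type == "off"]
  lfc <- left$time[left$type == "contact"]
  lfo <- left$time[left$type == "off"]
  if (length(rfc) < 2L) return(empty)

  # vectorized interleaving: place each within-stride event into its
  # RFC-to-RFC window and keep windows holding exactly one of each
  n_win <- length(rfc) - 1L
  place <- function(x) {
    x <- x[x > rfc[1] & x < rfc[length(rfc)]]
    win <- findInterval(x, rfc)
    cnt <- tabulate(win, n_win)
    val <- rep(NA_real_, n_win)
    val[win[cnt[win] == 1L]] <- x[cnt[win] == 1L]
    list(val = val, cnt = cnt)
  }
  p_lfo <- place(lfo)
  p_lfc <- place(lfc)
  p_rfo <- place(rfo)
  ok <- p_lfo$cnt == 1L & p_lfc$cnt == 1L & p_rfo$cnt == 1L &
    !is.na(p_lfo$val) & p_lfo$val < p_lfc$val & p_lfc$val < p_rfo$val
  ok[is.na(ok)] <- FALSE
  dropped <- n_win - sum(ok)
  if (dropped > 0L) {
    inform(sprintf("detect_gait_events: dropped %d stride(s) with malformed event interleaving",
                   dropped))
  }
  if (!any(ok)) return(empty)
  tibble::tibble(
    stride_index = seq_len(sum(ok)),
    rfc_s = rfc[seq_len(n_win)][ok],
    lfo_s = p_lfo$val[ok],
    lfc_s = p_lfc$val[ok],
    rfo_s = p_rfo$val[ok],
    stride_end_s = rfc[-1][ok],
    abnormal = FALSE
  )
}

#' Flag strides with abnormal gait-event latencies
#'
#' Marks strides whose inter-event latency deviates from the cohort of
#' strides by more than `k` standard deviations. The default basis is the
#' stride time (RFC to next RFC); `basis = "step"` additionally screens the
#' two step times (RFC to LFC and LFC to next RFC). A latency distribution
#' with zero SD yields no flags. No rows are removed.
#'
#' @param events Gait-event tibble from [detect_gait_events()].
#' @param k SD multiplier.
#' @param basis `"stride"` or `"step"`.
#' @return The events tibble with `abnormal` updated.
#' @export
flag_abnormal_latencies <- function(events, k = 4,
                                    basis = c("stride", "step")) {
  basis <- match.arg(basis)
  if (nrow(events) < 3L) {
    warn("fewer than 3 strides; no abnormal-latency flags assigned")
    events$abnormal <- FALSE
    return(events)
  }
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  stride_time <- events$stride_end_s - events$rfc_s
  flag <- abs(zscore(stride_time)) > k
  if (basis == "step") {
    step1 <- events$lfc_s - events$rfc_s
    step2 <- events$stride_end_s - events$lfc_s
    flag <- flag | abs(zscore(step1)) > k | abs(zscore(step2)) > k
  }
  flag[is.na(flag)] <- FALSE
  events$abnormal <- flag
  events
}
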