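#' Default analysis frequency grid
#'
#' 49 log-spaced frequencies spanning 2-50 Hz, slightly beyond the theta,
#' alpha and beta bands.
#'
#' @param n Number of frequencies.
#' @param lo,hi Band edges (Hz).
#' @return Numeric vector of frequencies (Hz).
#' @export
default_freqs <- function(n = 49, lo = 2, hi = 50) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Wavelet cycles as a function of frequency
#'
#' The number of cycles in the Morlet wavelet grows sublinearly with
#' frequency, `n(f) = c0 * (f / f0)^(1 - q)`, so time resolution improves
#' at high frequencies while low frequencies keep enough cycles for a
#' stable estimate. The defaults `(c0, q) = (3, 0.8)` give 3 cycles at the
#' 2 Hz grid floor and about 5.7 cycles at 50 Hz.
#'
#' @param freqs Frequencies (Hz).
#' @param c0 Cycles at the reference frequency.
#' @param q Expansion parameter in `[0, 1]`; `q = 1` keeps cycles constant,
#'   `q = 0` scales them linearly with frequency.
#' @param f0 Reference frequency (Hz).
#' @return Numeric vector of cycle counts.
#' @export
morlet_cycles <- function(freqs, c0 = 3, q = 0.8, f0 = 2) {
  c0 * (freqs / f0)^(1 - q)
}

# Complex Morlet transform of a full signal via frequency-domain filtering.
# Each analytic filter is the Fourier transform of a unit-peak-gain Morlet
# wavelet: a Gaussian of SD 1/(2*pi*sigma_t) centred on the wavelet
# frequency, applied to positive-frequency bins only. Returns a
# length(freqs) x length(x) complex matrix.
morlet_transform <- function(x, fs, freqs, cycles, pad_ratio = 2) {
  n <- length(x)
  sigma_t <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * max(sigma_t) * fs)
  nconv <- n + 2L * half
  nfft <- stats::nextn(pad_ratio * nconv, c(2L, 3L, 5L))
  xf <- fft(c(x, numeric(nfft - n)))
  bins <- 0:(nfft - 1)
  fgrid <- bins * fs / nfft
  pos <- fgrid <= fs / 2   # analytic filter: positive frequencies only
  out <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    g <- numeric(nfft)
    g[pos] <- exp(-2 * pi^2 * sigma_t[i]^2 * (fgrid[pos] - freqs[i])^2)
    conv <- fft(xf * g, inverse = TRUE) / nfft
    out[i, ] <- conv[seq_len(n)]
  }
  out
}

# half-length (s) of the longest wavelet on a frequency grid; epochs need
# this much context on each side
wavelet_half_length <- function(freqs, cycles) {
  3 * max(cycles / (2 * pi * freqs))
}

#' Per-stride gait-cycle spectral perturbation (wavelet power)
#'
#' Decomposes one source signal with complex Morlet wavelets whose cycle
#' count follows [morlet_cycles()], and extracts the log power of each
#' stride's samples. Each stride needs context of at least the half-length
#' of the longest wavelet on both sides; strides without enough context are
#' dropped with a message.
#'
#' @param signal Tibble with columns `time` and `value` (or a region
#'   column named by `region`).
#' @param events Gait-event tibble; one output element per row.
#' @param freqs Frequency grid (Hz).
#' @param cycles Cycle counts per frequency (defaults to
#'   [morlet_cycles()]).
#' @param pad_ratio Zero-padding factor of the convolution FFT.
#' @param region Optional column name holding the signal values.
#' @return List with `freqs`, and per stride `power_db` (freq x sample
#'   matrix of `10*log10` power), `times_s` (sample times) and the stride's
#'   event row; dropped strides are absent, with their indices in
#'   `dropped`.
#' @export
wavelet_ersp <- function(signal, events, freqs = default_freqs(),
                         cycles = morlet_cycles(freqs), pad_ratio = 2,
                         region = "value") {
  stopifnot("time" %in% names(signal), region %in% names(signal))
  fs <- infer_rate(signal$time)
  x <- signal[[region]]
  t0 <- signal$time[1]
  t1 <- signal$time[length(signal$time)]
  pad <- wavelet_half_length(freqs, cycles)

  keep <- which(events$rfc_s - pad >= t0 & events$stride_end_s + pad <= t1)
  dropped <- setdiff(seq_len(nrow(events)), keep)
  if (length(dropped)) {
    inform(sprintf("wavelet_ersp: dropped %d stride(s) without %0.2f s of wavelet context",
                   length(dropped), pad))
  }
  if (!length(keep)) return(list(freqs = freqs, strides = list(),
                                 dropped = dropped))
  # transform each temporally contiguous run of kept strides separately
  # (with full wavelet context), skipping long gaps between stride groups
  keep <- keep[order(events$rfc_s[keep])]
  gap_before <- c(Inf, events$rfc_s[keep[-1]] -
                    events$stride_end_s[keep[-length(keep)]])
  segment <- cumsum(gap_before > 2 * pad)
  strides <- vector("list", length(keep))
  for (seg in unique(segment)) {
    members <- keep[segment == seg]
    a <- min(events$rfc_s[members]) - pad
    b <- max(events$stride_end_s[members]) + pad
    i0 <- findInterval(a - 1e-12, signal$time) + 1L
    i1 <- findInterval(b + 1e-12, signal$time)
    tt <- signal$time[i0:i1]
    W <- morlet_transform(x[i0:i1], fs, freqs, cycles, pad_ratio)
    power_db <- 10 * log10(pmax(Mod(W)^2, .Machine$double.xmin))
    for (k in members) {
      j0 <- findInterval(events$rfc_s[k] - 1e-12, tt) + 1L
      j1 <- findInterval(events$stride_end_s[k] + 1e-12, tt)
      strides[[match(k, keep)]] <- list(
        power_db = power_db[, j0:j1, drop = FALSE],
        times_s = tt[j0:j1],
        events = events[k, ])
    }
  }
  list(freqs = freqs, strides = strides, dropped = dropped)
}

#' Single-trial full-epoch baseline removal
#'
#' Subtracts, per frequency, the stride's own mean log power across its
#' gait cycle. After this step every per-frequency time-mean is zero, which
#' makes strides comparable without a designated rest baseline and damps
#' the influence of globally noisy strides. An optional divisive variant
#' additionally scales by the within-stride SD of log power.
#'
#' @param power_db Frequency x time matrix of log power (dB).
#' @param divisive Also divide by the per-frequency SD across time.
#' @return Matrix of the same shape.
#' @export
single_trial_baseline <- function(power_db, divisive = FALSE) {
  mu <- rowMeans(power_db)
  out <- power_db - mu
  if (divisive) {
    s <- apply(power_db, 1, sd)
    s[!is.finite(s) | s == 0] <- 1
    out <- out / s
  }
  out
}

#' Canonical gait-event latencies from pooled strides
#'
#' For every stride in every supplied event table, each event's latency is
#' expressed as a fraction of that stride's cycle; the canonical latency of
#' an event is the median fraction across all pooled strides, in percent of
#' the gait cycle.
#'
#' @param event_tables A gait-event tibble or list of them (one per
#'   subject).
#' @return Named numeric vector `c(rfc = 0, lfo, lfc, rfo)` in percent.
#' @export
canonical_latencies <- function(event_tables) {
  if (is.data.frame(event_tables)) event_tables <- list(event_tables)
  pooled <- dplyr::bind_rows(event_tables)
  if (!nrow(pooled)) abort("no strides supplied")
  dur <- pooled$stride_end_s - pooled$rfc_s
  c(rfc = 0,
    lfo = 100 * stats::median((pooled$lfo_s - pooled$rfc_s) / dur),
    lfc = 100 * stats::median((pooled$lfc_s - pooled$rfc_s) / dur),
    rfo = 100 * stats::median((pooled$rfo_s - pooled$rfc_s) / dur))
}

#' Linearly time-warp a stride's map to the canonical gait cycle
#'
#' Builds the piecewise-linear monotone map of the stride's time axis that
#' sends its RFC, LFO, LFC, RFO and next-RFC to the canonical latencies
#' (0, lfo, lfc, rfo, 100 percent), then resamples every frequency row onto
#' a fixed percent-of-cycle grid by linear interpolation.
#'
#' @param power_db Frequency x sample matrix for one stride.
#' @param times_s Sample times of the columns (s).
#' @param events One-row gait-event tibble for the stride.
#' @param latencies Canonical latencies from [canonical_latencies()].
#' @param n_cols Number of columns of the canonical grid.
#' @return Frequency x `n_cols` matrix on the canonical grid.
#' @export
time_warp <- function(power_db, times_s, events,
                      latencies, n_cols = 200) {
  anchors_t <- c(events$rfc_s, events$lfo_s, events$lfc_s,
                 events$rfo_s, events$stride_end_s)
  if (any(diff(anchors_t) <= 0)) {
    abort("stride events must be strictly increasing")
  }
  anchors_pct <- c(0, latencies[["lfo"]], latencies[["lfc"]],
                   latencies[["rfo"]], 100)
  grid_pct <- seq(0, 100, length.out = n_cols)
  native_t <- stats::approx(anchors_pct, anchors_t, xout = grid_pct)$y
  # all rows share the same column-wise interpolation weights
  nt <- length(times_s)
  u <- stats::approx(times_s, seq_len(nt), xout = native_t, rule = 2)$y
  i0 <- pmin(pmax(floor(u), 1L), nt - 1L)
  f <- pmin(pmax(u - i0, 0), 1)
  sweep(power_db[, i0, drop = FALSE], 2, 1 - f, `*`) +
    sweep(power_db[, i0 + 1L, drop = FALSE], 2, f, `*`)
}

#' Construct a time-frequency map object
#'
#' @param values Frequency x time matrix of baseline-normalized log power
#'   (dB).
#' @param freqs Frequency grid (Hz).
#' @param latencies Canonical event latencies (percent of cycle).
#' @param n_strides Number of strides averaged into the map.
#' @return A `tf_map` object; `times` is the percent-of-cycle grid.
#' @export
new_tf_map <- function(values, freqs, latencies, n_strides = 1L) {
  stopifnot(is.matrix(values), nrow(values) == length(freqs))
  structure(list(
    freqs = freqs,
    times = seq(0, 100, length.out = ncol(values)),
    values = values,
    canonical_latencies = latencies,
    n_strides = as.integer(n_strides)
  ), class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs (%.1f-%.1f Hz) x %d cycle columns, %d stride(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$n_strides))
  invisible(x)
}

#' Average time-frequency maps
#'
#' Arithmetic mean per pixel over maps sharing a grid. At
#' `level = "within_subject"` the inputs are per-stride maps of one subject
#' and the stride counts accumulate; at `level = "across_subjects"` each
#' input is one subject's mean map and subjects are weighted equally
#' regardless of how many strides each contributed.
#'
#' @param maps List of `tf_map` objects with identical grids.
#' @param level Averaging level, see above.
#' @return A `tf_map`.
#' @export
average_maps <- function(maps, level = c("within_subject",
                                         "across_subjects")) {
  level <- match.arg(level)
  if (!length(maps)) abort("no maps to average")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(m$freqs, ref$freqs)) ||
        length(m$times) != length(ref$times)) {
      abort("maps must share identical frequency and time grids")
    }
  }
  vals <- Reduce(`+`, purrr::map(maps, "values")) / length(maps)
  n <- if (level == "within_subject") {
    sum(purrr::map_int(maps, "n_strides"))
  } else {
    ref$n_strides
  }
  new_tf_map(vals, ref$freqs, ref$canonical_latencies, n)
}

#' Mean power across a frequency band
#'
#' @param map A `tf_map`.
#' @param band Length-2 numeric, band edges in Hz (rows whose centre
#'   frequency falls inside the closed interval are averaged).
#' @return Tibble with `time_pct` and `power_db`.
#' @export
band_power <- function(map, band) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  rows <- which(map$freqs >= band[1] & map$freqs <= band[2])
  if (!length(rows)) abort("no frequency rows inside the requested band")
  tibble::tibble(time_pct = map$times,
                 power_db = colMeans(map$values[rows, , drop = FALSE]))
}

#' Subcondition-mean warped maps of one subject's source signal
#'
#' End-to-end spectral path for one session and one source region: wavelet
#' decomposition per stride, single-trial baseline, time-warping to the
#' canonical cycle, and averaging within each requested stride group.
#'
#' @param signal Tibble `time` + region column.
#' @param events Gait-event tibble.
#' @param groups Named list of integer vectors: for each group name, the
#'   rows of `events` to average.
#' @param latencies Canonical latencies (percent).
#' @param freqs Frequency grid.
#' @param n_cols Canonical grid columns.
#' @param region Column of `signal` holding the source values.
#' @param divisive_baseline Passed to [single_trial_baseline()].
#' @return Named list of `tf_map` objects (groups with no usable strides
#'   are `NULL`).
#' @export
session_ersp <- function(signal, events, groups, latencies,
                         freqs = default_freqs(), n_cols = 200,
                         region = "value", divisive_baseline = FALSE,
                         pad_ratio = 2) {
  ersp <- wavelet_ersp(signal, events, freqs = freqs, region = region,
                       pad_ratio = pad_ratio)
  kept_rows <- setdiff(seq_len(nrow(events)), ersp$dropped)
  warped <- purrr::map(ersp$strides, function(s) {
    time_warp(single_trial_baseline(s$power_db, divisive_baseline),
              s$times_s, s$events, latencies, n_cols)
  })
  purrr::map(groups, function(rows) {
    use <- which(kept_rows %in% rows)
    if (!length(use)) return(NULL)
    maps <- purrr::map(warped[use], function(v) {
      new_tf_map(v, freqs, latencies, 1L)
    })
    average_maps(maps, "within_subject")
  })
}
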