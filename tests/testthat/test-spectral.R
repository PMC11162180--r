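one_stride_events <- function(rfc = 0, dur = 1,
                              fr = c(lfo = 0.12, lfc = 0.5, rfo = 0.62)) {
  tibble::tibble(stride_index = 1L, rfc_s = rfc,
                 lfo_s = rfc + fr[["lfo"]] * dur,
                 lfc_s = rfc + fr[["lfc"]] * dur,
                 rfo_s = rfc + fr[["rfo"]] * dur,
                 stride_end_s = rfc + dur)
}

test_that("the wavelet decomposition localizes frequency and scales in dB", {
  fs <- 256
  t <- seq(0, 12, by = 1 / fs)
  sig <- tibble::tibble(time = t, value = sin(2 * pi * 6 * t))
  ev <- one_stride_events(rfc = 5, dur = 1.1)
  out <- wavelet_ersp(sig, ev)
  expect_length(out$strides, 1L)
  p <- out$strides[[1]]$power_db
  # frequency of maximum mean power: the grid bin nearest 6 Hz
  peak <- out$freqs[which.max(rowMeans(p))]
  expect_equal(peak, out$freqs[which.min(abs(out$freqs - 6))])

  sig2 <- tibble::tibble(time = t, value = 2 * sin(2 * pi * 6 * t))
  p2 <- wavelet_ersp(sig2, ev)$strides[[1]]$power_db
  expect_equal(p2 - p, matrix(10 * log10(4), nrow(p), ncol(p)),
               tolerance = 1e-9)
})

test_that("power of orthogonal sinusoids is additive away from their frequencies", {
  fs <- 256
  t <- seq(0, 12, by = 1 / fs)
  ev <- one_stride_events(rfc = 5, dur = 1.1)
  x1 <- sin(2 * pi * 5 * t)
  x2 <- sin(2 * pi * 20 * t)
  pw <- function(x) {
    out <- wavelet_ersp(tibble::tibble(time = t, value = x), ev)
    list(freqs = out$freqs, p = Mod(10^(out$strides[[1]]$power_db / 10)))
  }
  a <- pw(x1); b <- pw(x2); ab <- pw(x1 + x2)
  # keep rows where one component dominates: between the two frequencies
  # the interference term is comparable to the (negligible) total power,
  # and the bottom grid bins see finite-window leakage
  away <- (a$freqs > 2.4 & a$freqs < 3.5) | a$freqs > 30
  lhs <- rowMeans(ab$p)[away]
  rhs <- rowMeans(a$p + b$p)[away]
  expect_lt(max(abs(10 * log10(lhs / rhs))), 0.1)
})

test_that("white-noise input gives a time-flat mean power profile", {
  fs <- 128
  n_str <- 500
  t <- seq(0, n_str + 4, by = 1 / fs)
  withr::with_seed(33, x <- rnorm(length(t)))
  s0 <- 2 + 0:(n_str - 1)
  ev <- tibble::tibble(stride_index = seq_len(n_str), rfc_s = s0,
                       lfo_s = s0 + 0.12, lfc_s = s0 + 0.5,
                       rfo_s = s0 + 0.62, stride_end_s = s0 + 1)
  out <- wavelet_ersp(tibble::tibble(time = t, value = x), ev,
                      freqs = default_freqs(30), pad_ratio = 1)
  expect_length(out$strides, n_str)
  # average linear power over strides, then compare each frequency's time
  # profile to its own mean: deviations shrink as 1/sqrt(n_strides)
  nc <- min(vapply(out$strides, function(s) ncol(s$power_db), integer(1)))
  P <- Reduce(`+`, lapply(out$strides, function(s) {
    10^(s$power_db[, 1:nc] / 10)
  })) / n_str
  prof <- 10 * log10(P)
  dev <- prof - rowMeans(prof)
  expect_lt(max(abs(dev)), 1)
  expect_lt(median(abs(dev)), 0.3)
})

test_that("strides without wavelet context are dropped with a message", {
  fs <- 128
  t <- seq(0, 3, by = 1 / fs)
  sig <- tibble::tibble(time = t, value = rnorm(length(t)))
  ev <- dplyr::bind_rows(one_stride_events(rfc = 0.1, dur = 1),
                         one_stride_events(rfc = 1.4, dur = 1))
  expect_message(out <- wavelet_ersp(sig, ev), "dropped")
  expect_identical(out$dropped, 1:2)
})

test_that("single-trial baseline zeroes every per-frequency time-mean", {
  withr::with_seed(5, m <- matrix(rnorm(49 * 120, mean = 3), 49))
  b <- single_trial_baseline(m)
  expect_equal(rowMeans(b), rep(0, 49), tolerance = 1e-12)
  # constant map becomes exactly zero
  expect_equal(single_trial_baseline(matrix(2.5, 10, 20)),
               matrix(0, 10, 20))
  # shift invariance: a global dB offset does not change the output
  expect_equal(single_trial_baseline(m + 3), b)
  # divisive variant scales rows to unit SD
  d <- single_trial_baseline(m, divisive = TRUE)
  expect_equal(apply(d, 1, sd), rep(1, 49), tolerance = 1e-12)
})

test_that("canonical latencies are the pooled median event fractions", {
  ev1 <- dplyr::bind_rows(one_stride_events(0), one_stride_events(1, 1.2))
  lat <- canonical_latencies(ev1)
  expect_equal(unname(lat), c(0, 12, 50, 62))

  # oracle on a jittered pool across subjects
  tabs <- withr::with_seed(8, purrr::map(1:4, function(i) {
    dplyr::bind_rows(purrr::map(1:20, function(k) {
      fr <- c(lfo = runif(1, 0.08, 0.2), lfc = runif(1, 0.45, 0.55),
              rfo = runif(1, 0.58, 0.7))
      one_stride_events(rfc = k, dur = runif(1, 0.9, 1.3), fr = fr)
    }))
  }))
  lat <- canonical_latencies(tabs)
  pooled <- dplyr::bind_rows(tabs)
  dur <- pooled$stride_end_s - pooled$rfc_s
  expect_equal(lat[["lfo"]], 100 * median((pooled$lfo_s - pooled$rfc_s) / dur))
  expect_equal(lat[["lfc"]], 100 * median((pooled$lfc_s - pooled$rfc_s) / dur))
  # invariant to duplicating the stride pool
  expect_equal(canonical_latencies(c(tabs, tabs)), lat)
})

test_that("time-warping is exact at anchors and the identity on canonical strides", {
  lat <- c(rfc = 0, lfo = 12, lfc = 50, rfo = 62)
  ev <- one_stride_events(rfc = 0, dur = 1)
  tt <- seq(0, 1, length.out = 201)
  withr::with_seed(9, m <- matrix(rnorm(30 * 201), 30))
  w <- time_warp(m, tt, ev, lat, n_cols = 201)
  expect_equal(w, m, tolerance = 1e-9)

  # a stride with shifted events maps its event columns onto the canonical
  # latencies: the warp of the time axis itself must hit the anchors
  ev2 <- one_stride_events(rfc = 0, dur = 1,
                           fr = c(lfo = 0.2, lfc = 0.4, rfo = 0.7))
  time_row <- matrix(tt, 1)
  w2 <- time_warp(time_row, tt, ev2, lat, n_cols = 201)
  grid <- seq(0, 100, length.out = 201)
  for (evname in c("lfo", "lfc", "rfo")) {
    col <- which.min(abs(grid - lat[[evname]]))
    native <- switch(evname, lfo = 0.2, lfc = 0.4, rfo = 0.7)
    expect_equal(w2[1, col], native, tolerance = 1 / 200)
  }
  # warp is monotone for any valid event set
  expect_true(all(diff(w2[1, ]) >= -1e-12))
  bad <- ev2
  bad$lfo_s <- 0.6
  expect_error(time_warp(m[, 1:201, drop = FALSE], tt, bad, lat),
               "increasing")
})

test_that("map averaging is pixelwise with equal subject weights", {
  lat <- c(rfc = 0, lfo = 12, lfc = 50, rfo = 62)
  withr::with_seed(10, v <- matrix(rnorm(5 * 8), 5))
  f <- default_freqs(5, 4, 30)
  m1 <- new_tf_map(v, f, lat, 10L)
  expect_equal(average_maps(list(m1))$values, v)
  m2 <- new_tf_map(-v, f, lat, 2L)
  avg <- average_maps(list(m1, m2))
  expect_equal(avg$values, matrix(0, 5, 8))
  expect_identical(avg$n_strides, 12L)
  m3 <- new_tf_map(v * 0 + 3, f, lat, 1L)
  g <- average_maps(list(new_tf_map(v * 0 + 1, f, lat, 5L),
                         new_tf_map(v * 0 + 2, f, lat, 50L), m3),
                    level = "across_subjects")
  expect_equal(g$values, matrix(2, 5, 8))
  wrong <- new_tf_map(matrix(0, 4, 8), default_freqs(4, 4, 30), lat)
  expect_error(average_maps(list(m1, wrong)), "identical")
})

test_that("band power averages the rows inside the band", {
  lat <- c(rfc = 0, lfo = 12, lfc = 50, rfo = 62)
  f <- c(3, 5, 7, 10, 20)
  vals <- matrix(0, 5, 4)
  vals[4, ] <- 6   # power only at 10 Hz
  m <- new_tf_map(vals, f, lat)
  expect_equal(band_power(m, c(4, 7))$power_db, rep(0, 4))
  expect_equal(band_power(m, c(8, 12))$power_db, rep(6, 4))
  m1 <- new_tf_map(matrix(1, 5, 4), f, lat)
  expect_equal(band_power(m1, c(2, 50))$power_db, rep(1, 4))
  expect_equal(band_power(m1, range(f))$power_db,
               colMeans(matrix(1, 5, 4)))
  expect_error(band_power(m, c(25, 30)), "band")
})

test_that("an injected gait-locked theta burst appears at its cycle position", {
  # strong burst against mild background, warped on the true event times so
  # the check isolates the spectral path from event-detection bias
  sched <- ramp_only_schedule()
  spec <- tibble::tibble(region = "left_acc", band_lo = 4, band_hi = 7,
                         gait_phase_center = 40, phase_width = 20,
                         gain_vs_error = 0, baseline_amplitude = 4)
  cfg <- synthetic_config(burst_spec = spec, source_noise_sd = 0.5,
                          seed = 17)
  sess <- simulate_session(sched, cfg, signals = "sources")
  tr <- sess$truth$strides
  lat <- canonical_latencies(tr)
  rows <- list(all = 10:70)
  maps <- suppressMessages(
    session_ersp(sess$sources, tr, rows, lat, region = "left_acc"))
  bp <- band_power(maps$all, c(4, 7))
  peak_pct <- bp$time_pct[which.max(bp$power_db)]
  # burst injected at 40% of the cycle; +-3 grid columns of 200
  expect_lt(abs(peak_pct - 40), 3 * 100 / 200 + 1e-9)
})

test_that("baseline offsets per stride cancel in condition contrasts", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  withr::with_seed(12, x <- rnorm(length(t)))
  ev <- dplyr::bind_rows(purrr::map(5:20, function(k) {
    one_stride_events(rfc = k, dur = 1)
  }))
  lat <- c(rfc = 0, lfo = 12, lfc = 50, rfo = 62)
  groups <- list(a = 1:8, b = 9:16)
  base <- session_ersp(tibble::tibble(time = t, value = x), ev, groups, lat,
                       n_cols = 100)
  # scaling the signal per condition-of-interest by a constant factor adds
  # a constant dB offset per stride, which the single-trial baseline removes
  x2 <- x * 3
  scaled <- session_ersp(tibble::tibble(time = t, value = x2), ev, groups,
                         lat, n_cols = 100)
  diff_base <- base$a$values - base$b$values
  diff_scaled <- scaled$a$values - scaled$b$values
  expect_equal(diff_scaled, diff_base, tolerance = 1e-8)
})
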