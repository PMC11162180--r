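test_that("asymmetry ratios are antisymmetric, bounded and handle degenerate sums", {
  expect_equal(compute_sla(0.5, 0.5), 0)
  expect_equal(compute_sla(0.6, 0.4), 0.2)
  expect_equal(compute_belt_symmetry(1.2, 0.6), 1 / 3)
  expect_equal(compute_belt_symmetry(0.9, 0.9), 0)
  expect_equal(compute_belt_symmetry(0.7, 0), 1)
  expect_true(is.na(compute_sla(0, 0)))
  expect_true(is.na(compute_belt_symmetry(-1, 1)))

  withr::with_seed(1, {
    f <- runif(500, 0.01, 2)
    s <- runif(500, 0.01, 2)
  })
  expect_equal(compute_sla(f, s), -compute_sla(s, f))
  expect_true(all(abs(compute_sla(f, s)) < 1))
  expect_true(all(abs(compute_belt_symmetry(f, s)) <= 1))
})

test_that("baseline normalization centres the baseline window at zero", {
  withr::with_seed(2, sla <- rnorm(200, 0.03, 0.01))
  base <- 1:30
  out <- normalize_sla(sla, base)
  expect_equal(mean(out[base]), 0)
  expect_equal(out, sla - mean(sla[base]))
  expect_equal(normalize_sla(rep(0.03, 50), 1:30), rep(0, 50))
  expect_error(normalize_sla(sla, integer(0)), "empty")
})

test_that("step lengths come from the marker separation at foot contact", {
  t <- seq(0, 10, by = 0.01)
  ev <- tibble::tibble(stride_index = 1:5, rfc_s = 1:5 + 0.0,
                       lfo_s = 1:5 + 0.1, lfc_s = 1:5 + 0.5,
                       rfo_s = 1:5 + 0.6, stride_end_s = 1:5 + 1.0)
  frozen <- tibble::tibble(time = t, left_ap = 0, right_ap = 0.3)
  sl <- compute_step_lengths(frozen, ev)
  expect_equal(sl$step_length_fast, rep(0.3, 5))
  expect_equal(sl$step_length_slow, rep(0.3, 5))
  coincident <- tibble::tibble(time = t, left_ap = 0.1, right_ap = 0.1)
  sl0 <- compute_step_lengths(coincident, ev)
  expect_equal(sl0$step_length_fast, rep(0, 5))
  # event outside the marker range: missing value
  late <- ev
  late$rfc_s[5] <- 11
  expect_true(is.na(compute_step_lengths(frozen, late)$step_length_fast[5]))
})

test_that("marker velocity during stance recovers the belt speed", {
  t <- seq(0, 10, by = 0.01)
  ev <- tibble::tibble(stride_index = 1:8, rfc_s = 1:8 + 0.0,
                       lfo_s = 1:8 + 0.12, lfc_s = 1:8 + 0.5,
                       rfo_s = 1:8 + 0.62, stride_end_s = 1:8 + 1.0)
  moving <- tibble::tibble(time = t, left_ap = -1.2 * t, right_ap = -1.2 * t)
  sp <- estimate_belt_speeds(moving, ev)
  expect_equal(sp$belt_speed_fast, rep(1.2, 8), tolerance = 1e-9)
  expect_equal(sp$belt_speed_slow, rep(1.2, 8), tolerance = 1e-9)
  still <- tibble::tibble(time = t, left_ap = 0.2, right_ap = -0.1)
  sp0 <- estimate_belt_speeds(still, ev)
  expect_equal(sp0$belt_speed_fast, rep(0, 8))

  # synthetic tied phase: both belts near 0.9 m/s (skip the first strides
  # of the phase, where the 6-stride smoothing window still carries the
  # preceding faster block)
  stt <- fixture_stride_table()
  tied <- stt[stt$phase_label == "pre_medium", ]
  tied <- tied[-(1:6), ]
  expect_true(all(abs(tied$belt_speed_fast - 0.9) < 0.02))
  expect_true(all(abs(tied$belt_speed_slow - 0.9) < 0.02))
})

test_that("belt-series conditioning interpolates, smooths and replaces outliers", {
  expect_equal(condition_belt_series(rep(1.2, 40)), rep(1.2, 40))
  # idempotence on an already-clean constant series
  expect_equal(condition_belt_series(condition_belt_series(rep(0.9, 20))),
               rep(0.9, 20))

  # interior missing values are linearly interpolated before smoothing:
  # inside a constant series the gap refills exactly
  x <- c(rep(1.2, 10), NA, rep(1.2, 10))
  expect_equal(condition_belt_series(x), rep(1.2, 21))
  # between a 1.0 plateau and a 1.2 plateau the gap midpoint becomes 1.1;
  # check on the interpolation output via a window where smoothing has
  # settled on the left plateau
  x2 <- c(rep(1.0, 12), NA, rep(1.2, 12))
  out2 <- condition_belt_series(x2)
  expect_equal(out2[12], 1.0)      # left plateau untouched
  expect_gt(out2[13], 1.0)         # interpolated 1.1 enters the average
  expect_equal(out2[25], 1.2, tolerance = 1e-9)  # right plateau settles

  # single large spike in a constant series is flagged as a local outlier
  # and replaced by the mean of its neighbours; oracle applies the same
  # sliding 6-element window by brute force
  y <- rep(1, 60)
  y[30] <- 10
  sm <- numeric(60)
  for (i in 1:60) {
    j <- max(1, i - 5)
    sm[i] <- mean(y[j:i])
  }
  out_flags <- logical(60)
  for (i in 1:60) {
    w <- sm[max(1, i - 3):min(60, i + 2)]
    if (sd(w) > 0 && abs(sm[i] - mean(w)) > 3 * sd(w)) out_flags[i] <- TRUE
  }
  oracle <- sm
  for (i in which(out_flags)) {
    nb <- c(max(which(!out_flags[1:(i - 1)])), i + min(which(!out_flags[(i + 1):60])))
    oracle[i] <- mean(sm[nb])
  }
  expect_equal(condition_belt_series(y), oracle)
  expect_error(condition_belt_series(rep(NA_real_, 10)), "missing")
  expect_error(condition_belt_series(c(1, 2)), "at least 6")
})

test_that("the 2-SD reference criterion flags asymmetric strides", {
  crit <- asymmetry_criterion(c(rnorm(10), rep(0, 25), rep(0.02, 5)))
  expect_identical(crit$n_reference, 30L)
  expect_error(asymmetry_criterion(rnorm(20)), "at least 30")

  crit <- structure(list(mu = 0, sigma = 0.01, k = 2, n_reference = 30L),
                    class = "asym_criterion")
  expect_true(detect_asymmetric_strides(0.025, crit))
  expect_true(detect_asymmetric_strides(-0.025, crit))
  expect_false(detect_asymmetric_strides(0.015, crit))
  expect_identical(detect_asymmetric_strides(c(0.05, NA, 0.001), crit),
                   c(TRUE, FALSE, FALSE))
})

test_that("median split separates large from small errors with deterministic ties", {
  sla <- c(0.03, 0.05, 0.07, 0.09)
  cls <- median_split_errors(sla, rep(TRUE, 4))
  expect_identical(as.character(cls), c("small", "small", "large", "large"))

  # all equal: everything small
  cls_eq <- median_split_errors(rep(0.05, 6), rep(TRUE, 6))
  expect_identical(unique(as.character(cls_eq)), "small")

  # odd count: the median element goes to small
  cls_odd <- median_split_errors(c(0.03, 0.05, 0.07), rep(TRUE, 3))
  expect_identical(as.character(cls_odd), c("small", "small", "large"))

  # non-asymmetric strides stay none; sign is ignored
  cls_mix <- median_split_errors(c(-0.09, 0.01, 0.03, 0.05),
                                 c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(as.character(cls_mix), c("large", "none", "small", "small"))

  expect_warning(none <- median_split_errors(c(0.1, 0.2), c(TRUE, FALSE)),
                 "fewer than 2")
  expect_identical(unique(as.character(none)), "none")
})

# independent brute-force scan: try every possible run start
steady_state_oracle <- function(sla, window = 30, run_length = 10, k = 2) {
  mu <- mean(tail(sla, window))
  s <- sd(tail(sla, window))
  inband <- abs(sla - mu) <= k * s
  for (i in seq_len(length(sla) - run_length + 1)) {
    if (all(inband[i:(i + run_length - 1)])) return(i)
  }
  NA_integer_
}

test_that("steady-state detection equals the exhaustive scan", {
  expect_identical(detect_steady_state(rep(0.1, 50)), 1L)
  expect_error(detect_steady_state(rnorm(30)), "too short")

  # out-of-band until the terminal window
  s1 <- c(rep(1, 60), rep(0, 40))
  expect_identical(detect_steady_state(s1), steady_state_oracle(s1))
  expect_identical(detect_steady_state(s1), 61L)

  # alternating in/out pattern with short runs before the last 30
  s2 <- c(rep(c(0, 5), 30), rep(0, 40))
  expect_identical(detect_steady_state(s2), steady_state_oracle(s2))

  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(40:120, 1)
      series <- rnorm(n) + c(rep(sample(c(0, 3), 1), n - 30), rep(0, 30))
      expect_identical(detect_steady_state(series),
                       steady_state_oracle(series))
    }
  })
})

test_that("performance scores normalize to [0,1], invert, and regress", {
  perf <- tibble::tibble(
    subject = sprintf("s%02d", 1:5),
    strides_to_steady_state = c(12L, 40L, 25L, 60L, 33L),
    pct_asymmetric = c(10, 80, 35, 20, 55)
  )
  ps <- performance_metrics(perf)
  sc <- tidy(ps)
  expect_equal(sc$abrupt_score[1], 1)   # cohort minimum strides
  expect_equal(sc$abrupt_score[4], 0)
  expect_equal(sc$gradual_score[2], 0)  # cohort maximum error rate
  expect_true(all(sc$abrupt_score >= 0 & sc$abrupt_score <= 1))
  g <- glance(ps)
  expect_true(all(c("slope", "adj_r_squared", "p_value") %in% names(g)))
  expect_error(performance_metrics(perf[1, ]), "at least 2")
  expect_error(performance_metrics(perf[, 1:2]), "missing columns")
})

test_that("uncorrelated scores rarely yield a significant regression", {
  # null Monte-Carlo at the study's sample size
  reject <- withr::with_seed(77, {
    vapply(1:100, function(i) {
      perf <- tibble::tibble(
        subject = as.character(1:29),
        strides_to_steady_state = sample(10:200, 29, replace = TRUE),
        pct_asymmetric = runif(29, 0, 100)
      )
      glance(performance_metrics(perf))$p_value < 0.05
    }, logical(1))
  })
  expect_lte(mean(reject), 0.10)
})

test_that("detected asymmetric flags agree with the generator's ground truth", {
  sess <- fixture_session()
  stt <- fixture_stride_table()
  tr <- sess$truth$strides
  # align detected strides to true strides and re-apply the criterion to
  # the true SLA series using the detected reference window
  idx <- vapply(stt$rfc_s, function(x) which.min(abs(tr$rfc_s - x)),
                integer(1))
  ref_rows <- which(stt$subcondition == "pre_gradual")
  crit <- asymmetry_criterion(tr$sla[idx[ref_rows]])
  flags_true <- detect_asymmetric_strides(tr$sla[idx], crit)
  expect_identical(flags_true, sess$truth$flags[idx])
  # the marker-derived flags agree on all but boundary cases
  expect_gt(mean(stt$is_asymmetric == flags_true), 0.95)
})
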