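#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data
#' @importFrom stats approx median qt sd rnorm runif fft lm coef
#' @importFrom utils head tail
NULL

# infer a constant sampling rate (Hz) from a time vector
infer_rate <- function(time) {
  dt <- diff(time)
  if (length(dt) < 1L || any(dt <= 0)) {
    abort("time vector must be strictly increasing with >= 2 samples")
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    warn("time vector is not uniformly sampled; using median spacing")
  }
  1 / stats::median(dt)
}

# linear interpolation that returns NA outside the observed range
interp_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 1)$y
}

# cumulative trapezoidal integral of y over x, same length as x, starts at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

# greatest common divisor (for rational resampling factors)
gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
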