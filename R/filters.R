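#' Low-pass filter specification
#'
#' Describes the Butterworth low-pass designs used by the pipeline: 4th
#' order, 30 Hz cut-off for GRF and 20 Hz for sacral acceleration, applied
#' zero-phase (forward-backward), which doubles the effective attenuation.
#'
#' @param cutoff_hz Cut-off frequency in Hz.
#' @param order Filter order (default 4).
#' @param phase `"zero"` for forward-backward filtering (the default and
#'   the only implemented option).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(cutoff_hz, order = 4L, phase = "zero") {
  stopifnot(is.numeric(cutoff_hz), length(cutoff_hz) == 1L, cutoff_hz > 0,
            order >= 1L, identical(phase, "zero"))
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 family = "butterworth", phase = phase),
            class = "filter_spec")
}

# Digital Butterworth low-pass (b, a) via bilinear transform of the analog
# all-pole prototype. DC gain forced to exactly 1.
butter_lowpass <- function(order, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoff_hz, rate_hz / 2))
  n <- as.integer(order)
  k <- seq_len(n)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * rate_hz
  wc <- fs2 * tan(pi * cutoff_hz / rate_hz)  # prewarped cutoff (rad/s)
  p <- wc * p
  zp <- (fs2 + p) / (fs2 - p)                # bilinear-transformed poles
  gain <- Re(wc^n / prod(fs2 - p))
  a <- Re(poly_from_roots(zp))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, n)))
  b <- b * sum(a) / sum(b)                   # exact unit DC gain
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, highest degree first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

# Direct-form II transposed IIR filter with initial conditions zi.
# Returns list(y, zf).
lfilter <- function(b, a, x, zi = NULL) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, m) else as.numeric(zi)
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z[1]
    if (m > 1L)
      for (j in seq_len(m - 1L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * yi
    z[m] <- b[m + 1L] * x[i] - a[m + 1L] * yi
    y[i] <- yi
  }
  list(y = y, zf = z)
}

# Steady-state initial conditions for a unit-amplitude step input, so that
# filtering a constant produces that constant exactly from sample one.
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, m, m)               # companion matrix of a, transposed
  comp[1, ] <- -a[-1]
  if (m > 1L) comp[cbind(2:m, 1:(m - 1L))] <- 1
  A <- t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - A, B)
}

# Zero-phase filtering with odd-reflection edge padding (scipy-style).
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  edge <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= edge)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 edge))
  ext <- c(2 * x[1] - x[(edge + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - edge)])
  zi <- lfilter_zi(b, a)
  fwd <- lfilter(b, a, ext, zi * ext[1])$y
  rev1 <- rev(fwd)
  bwd <- lfilter(b, a, rev1, zi * rev1[1])$y
  rev(bwd)[(edge + 1L):(edge + n)]
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Filters a trace forward and backward with the requested Butterworth
#' design, giving zero phase distortion and unit DC gain. Length and rate
#' are preserved.
#'
#' @param trace A [signal_trace()].
#' @param spec A [filter_spec()], or a cutoff frequency in Hz.
#' @param order Filter order when `spec` is given as a plain cutoff.
#' @return A filtered `signal_trace`.
#' @export
lowpass <- function(trace, spec, order = 4L) {
  stopifnot(is_signal_trace(trace))
  if (!inherits(spec, "filter_spec")) spec <- filter_spec(spec, order = order)
  ba <- butter_lowpass(spec$order, spec$cutoff_hz, trace$rate)
  retrace(trace, filtfilt_ba(ba$b, ba$a, trace$samples))
}

#' Anti-aliased integer-factor downsampling
#'
#' Decimates a trace to `target_rate` after a zero-phase Butterworth
#' anti-aliasing filter (4th order, cut-off at 0.4 x target rate, applied
#' forward-backward). The source rate must be an integer multiple of the
#' target rate; output length is `ceiling(n * target/source)`.
#'
#' @param trace A [signal_trace()].
#' @param target_rate Target sampling rate in Hz.
#' @return The decimated `signal_trace` with its rate field updated.
#' @export
downsample <- function(trace, target_rate) {
  stopifnot(is_signal_trace(trace))
  q <- trace$rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf(
      "downsample: source rate %g Hz is not an integer multiple of target rate %g Hz",
      trace$rate, target_rate))
  q <- as.integer(round(q))
  if (q == 1L) return(trace)
  ba <- butter_lowpass(4L, 0.4 * target_rate, trace$rate)
  y <- filtfilt_ba(ba$b, ba$a, trace$samples)
  retrace(trace, y[seq(1L, length(y), by = q)], rate = target_rate)
}
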