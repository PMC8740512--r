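#' Construct a uniformly sampled signal trace
#'
#' The universal single-channel container used throughout the package: a
#' numeric sample vector plus its sampling rate, an axis label identifying
#' what was measured, and a unit label.
#'
#' @param samples Numeric vector of finite samples (length >= 1).
#' @param rate Sampling rate in Hz (> 0).
#' @param axis One of `"grf_normal_BW"`, `"acc_vertical"`,
#'   `"acc_anteroposterior"`.
#' @param units Unit label, typically `"BW"`, `"N"`, or `"m/s^2"`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, axis = c("grf_normal_BW",
                         "acc_vertical", "acc_anteroposterior"),
                         units = "BW") {
  axis <- match.arg(axis)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal_trace: need at least one sample")
  if (!all(is.finite(samples))) stop("signal_trace: non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("signal_trace: rate must be a single positive number")
  structure(list(samples = samples, rate = rate, axis = axis, units = units),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s [%s], %d samples @ %g Hz (%.3f s)\n",
              x$axis, x$units, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

# internal: clone a trace with new samples (and optionally rate/units)
retrace <- function(x, samples, rate = x$rate, units = x$units) {
  structure(list(samples = as.numeric(samples), rate = rate, axis = x$axis,
                 units = units), class = "signal_trace")
}

is_signal_trace <- function(x) inherits(x, "signal_trace")
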