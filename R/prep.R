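#' Normalize a GRF trace to bodyweights
#'
#' Divides a force trace in Newtons by `mass * g` (g = 9.81 m/s^2).
#'
#' @param grf A [signal_trace()] in Newtons.
#' @param mass Body mass in kg (> 0).
#' @return The trace in BW units.
#' @export
normalize_bw <- function(grf, mass) {
  stopifnot(is_signal_trace(grf))
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("normalize_bw: mass must be a single positive number")
  retrace(grf, grf$samples / (mass * GRAVITY), units = "BW")
}

#' Replace negative samples with zero
#'
#' Applied to the filtered vertical acceleration channel: vertical
#' centre-of-mass acceleration is negative throughout the aerial phase, and
#' zeroing it helps the network keep predicted aerial-phase GRF at zero.
#'
#' @param trace A [signal_trace()].
#' @return The clipped trace (`max(x, 0)` elementwise).
#' @export
clip_negative <- function(trace) {
  stopifnot(is_signal_trace(trace))
  retrace(trace, pmax(trace$samples, 0))
}

#' Build overlapping per-frame acceleration windows
#'
#' For each frame t of the (equal-length) acceleration traces, extracts the
#' 6-frame window spanning source frames t-3 .. t+2, after padding the
#' trial with 3 copies of the first value and 2 copies of the last value.
#' The window count therefore always equals the GRF frame count.
#'
#' @param acc_v,acc_ap Vertical and anteroposterior [signal_trace()]s of
#'   equal length and rate.
#' @param width Window width in frames (default 6).
#' @return A `windowed_acc` object: list of two `T x width` matrices
#'   (`v`, `ap`), plus rate and padding bookkeeping.
#' @export
make_windows <- function(acc_v, acc_ap, width = 6L) {
  stopifnot(is_signal_trace(acc_v), is_signal_trace(acc_ap))
  if (length(acc_v) != length(acc_ap) || acc_v$rate != acc_ap$rate)
    stop("make_windows: acceleration traces must share length and rate")
  n <- length(acc_v)
  if (n < 1L) stop("make_windows: empty trace")
  width <- as.integer(width)
  lead <- width %/% 2L         # 3 for width 6
  trail <- width - lead - 1L   # 2 for width 6
  win_one <- function(x) {
    padded <- c(rep(x[1], lead), x, rep(x[n], trail))
    idx <- outer(seq_len(n), 0:(width - 1L), `+`)
    matrix(padded[idx], nrow = n, ncol = width)
  }
  structure(list(v = win_one(acc_v$samples), ap = win_one(acc_ap$samples),
                 rate = acc_v$rate, lead = lead, trail = trail,
                 width = width),
            class = "windowed_acc")
}

#' Run the full signal-processing pipeline on one trial
#'
#' Downsamples GRF and both acceleration channels to `rate`, normalizes the
#' GRF to BW if it arrives in Newtons, low-pass filters the GRF at
#' `grf_cutoff_hz` and the accelerations at `acc_cutoff_hz` (4th-order
#' zero-phase Butterworth), and zero-clips the vertical acceleration.
#'
#' @param trial A `gait_trial` (GRF optional).
#' @param rate Target rate, Hz (default 500).
#' @param grf_cutoff_hz,acc_cutoff_hz Filter cut-offs in Hz (30 / 20).
#' @return The processed `gait_trial`.
#' @export
preprocess_trial <- function(trial, rate = 500, grf_cutoff_hz = 30,
                             acc_cutoff_hz = 20) {
  stopifnot(inherits(trial, "gait_trial"))
  out <- trial
  if (!is.null(trial$grf)) {
    g <- downsample(trial$grf, rate)
    if (identical(g$units, "N")) g <- normalize_bw(g, trial$meta$mass)
    out$grf <- lowpass(g, grf_cutoff_hz)
  }
  av <- lowpass(downsample(trial$acc_v, rate), acc_cutoff_hz)
  out$acc_v <- clip_negative(av)
  out$acc_ap <- lowpass(downsample(trial$acc_ap, rate), acc_cutoff_hz)
  out
}
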