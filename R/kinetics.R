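#' Segment stance phases by bodyweight threshold
#'
#' Identifies foot-ground contacts as maximal runs of samples strictly
#' above `threshold` BW. Optional debouncing (on by default) merges aerial
#' gaps shorter than `min_gap_ms` and drops contacts shorter than
#' `min_contact_ms`, which suppresses threshold chatter on noisy predicted
#' waveforms; raw thresholding is recovered with `debounce = FALSE`.
#'
#' @param grf A [signal_trace()] in BW.
#' @param threshold Stance threshold in BW (default 0.05).
#' @param debounce Apply the merge/drop rules?
#' @param min_contact_ms Minimum contact duration kept (ms).
#' @param min_gap_ms Minimum aerial gap kept (ms).
#' @return A `stance_segmentation`: data frame of half-open frame
#'   intervals `[start, end)` (1-based), with the threshold and rate
#'   attached as attributes. Zero rows when no contact is found.
#' @export
segment_stance <- function(grf, threshold = 0.05, debounce = TRUE,
                           min_contact_ms = 25, min_gap_ms = 10) {
  stopifnot(is_signal_trace(grf))
  x <- grf$samples > threshold
  n <- length(x)
  d <- diff(c(FALSE, x, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L)          # end is one past the last in-stance frame
  seg <- data.frame(start = starts, end = ends)
  if (debounce && nrow(seg) > 1L) {
    min_gap <- min_gap_ms / 1000 * grf$rate
    keep <- list(seg[1, ])
    for (i in seq_len(nrow(seg))[-1]) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end < min_gap) {
        keep[[length(keep)]]$end <- seg$end[i]
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  if (debounce && nrow(seg) > 0L) {
    min_len <- min_contact_ms / 1000 * grf$rate
    seg <- seg[(seg$end - seg$start) >= min_len, , drop = FALSE]
  }
  rownames(seg) <- NULL
  structure(seg, threshold = threshold, rate = grf$rate,
            class = c("stance_segmentation", "data.frame"))
}

# linear interpolation of the trace value `ms` after contact onset
value_at_offset <- function(samples, start, offset_s, rate) {
  pos <- (start - 1) + offset_s * rate        # 0-based fractional frame
  lo <- floor(pos); hi <- ceiling(pos)
  if (hi + 1 > length(samples)) return(NA_real_)
  w <- pos - lo
  (1 - w) * samples[lo + 1] + w * samples[hi + 1]
}

round_half_up <- function(x) floor(x + 0.5)

#' Discrete biomechanical variables from a segmented GRF waveform
#'
#' Per contact: the active peak (maximum GRF within 40-60% of stance, the
#' window that excludes early-stance impact peaks), impulse (trapezoidal
#' integral of GRF over stance), loading rate (secant slope over the first
#' 25 ms of stance, linearly interpolated at non-integer frame offsets and
#' `NA` for contacts shorter than 25 ms), and contact time. Per trial: step
#' frequency as contact onsets per second of trial duration.
#'
#' @param grf The [signal_trace()] the segmentation came from (BW).
#' @param seg A [segment_stance()] result.
#' @return A `step_kinetics` object: `steps` data frame (one row per
#'   contact: `active_peak` BW, `impulse` BW.s, `loading_rate` BW/s,
#'   `contact_time` ms) and scalar `step_freq` (Hz).
#' @export
discrete_variables <- function(grf, seg) {
  stopifnot(is_signal_trace(grf), inherits(seg, "stance_segmentation"))
  rate <- grf$rate
  x <- grf$samples
  steps <- lapply(seq_len(nrow(seg)), function(i) {
    s <- seg$start[i]; e <- seg$end[i]
    L <- e - s                                   # frame count
    frames <- x[s:(e - 1)]
    i_lo <- min(L - 1, round_half_up(0.40 * L))  # 0-based offsets, inclusive
    i_hi <- min(L - 1, round_half_up(0.60 * L))
    active_peak <- max(frames[(i_lo:i_hi) + 1])
    impulse <- sum((frames[-1] + frames[-L]) / 2) / rate
    lr <- NA_real_
    if (L / rate >= 0.025) {
      f25 <- value_at_offset(x, s, 0.025, rate)
      if (!is.na(f25)) lr <- (f25 - x[s]) / 0.025
    }
    data.frame(start = s, end = e, contact_time = L / rate * 1000,
               active_peak = active_peak, impulse = impulse,
               loading_rate = lr)
  })
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(start = integer(0), end = integer(0),
               contact_time = numeric(0), active_peak = numeric(0),
               impulse = numeric(0), loading_rate = numeric(0))
  duration <- length(x) / rate
  structure(list(steps = steps, step_freq = nrow(steps) / duration,
                 duration = duration, rate = rate),
            class = "step_kinetics")
}

#' @export
print.step_kinetics <- function(x, ...) {
  cat(sprintf("<step_kinetics> %d contacts, step frequency %.2f Hz\n",
              nrow(x$steps), x$step_freq))
  if (nrow(x$steps)) print(utils::head(x$steps, 5), ...)
  invisible(x)
}

#' Biomechanical boundary checks on a predicted waveform
#'
#' Two plausibility criteria decide whether a predicted GRF waveform is
#' usable: (1) in validation mode (a measured waveform supplied) the
#' predicted waveform must contain the same number of foot-ground contacts
#' as the measured one at the same 5% BW threshold; (2) the step frequency
#' of the predicted waveform must be at most `max_step_freq` (4 Hz passes).
#' Trials failing either are flagged for exclusion and count toward the
#' cohort failure rate.
#'
#' @param pred Predicted [signal_trace()] in BW.
#' @param measured Measured `signal_trace` in BW, or `NULL` in
#'   prediction-only mode (criterion 1 then vacuously passes).
#' @param max_step_freq Upper bound on predicted step frequency (Hz).
#' @param threshold Stance threshold (BW).
#' @param ... Passed to [segment_stance()] (debounce settings).
#' @return A `boundary_verdict` list: `contact_count_ok`, `step_freq_ok`,
#'   `passed`, counts and a diagnostics string.
#' @export
check_boundaries <- function(pred, measured = NULL, max_step_freq = 4,
                             threshold = 0.05, ...) {
  stopifnot(is_signal_trace(pred))
  seg_p <- segment_stance(pred, threshold, ...)
  n_pred <- nrow(seg_p)
  sf <- n_pred / (length(pred) / pred$rate)
  contact_ok <- TRUE
  n_meas <- NA_integer_
  if (!is.null(measured)) {
    stopifnot(is_signal_trace(measured))
    if (measured$rate != pred$rate)
      stop("check_boundaries: rate mismatch between predicted and measured traces")
    n_meas <- nrow(segment_stance(measured, threshold, ...))
    contact_ok <- n_pred == n_meas
  }
  sf_ok <- sf <= max_step_freq
  structure(list(
    contact_count_ok = contact_ok, step_freq_ok = sf_ok,
    passed = contact_ok && sf_ok,
    n_contacts_pred = n_pred, n_contacts_meas = n_meas, step_freq = sf,
    diagnostics = sprintf(
      "predicted %d contacts%s, step frequency %.2f Hz (limit %g)",
      n_pred,
      if (is.na(n_meas)) "" else sprintf(" vs %d measured", n_meas),
      sf, max_step_freq)),
    class = "boundary_verdict")
}

#' @export
print.boundary_verdict <- function(x, ...) {
  cat(sprintf("<boundary_verdict> %s: %s\n",
              if (x$passed) "PASS" else "FAIL", x$diagnostics))
  invisible(x)
}
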