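FEATURE_NAMES <- c("mean_v", "sd_v", "range_v", "mean_ap", "sd_ap",
                   "range_ap", "mass", "height", "speed", "slope",
                   "fs_rear", "fs_mid", "fs_fore")

#' Summary statistics of one acceleration window
#'
#' Mean, population standard deviation (divisor n), and range (max - min)
#' of a single window.
#'
#' @param window Numeric vector (one window, one axis).
#' @return Named numeric vector `c(mean, sd, range)`.
#' @export
window_stats <- function(window) {
  stopifnot(all(is.finite(window)))
  m <- mean(window)
  c(mean = m,
    sd = sqrt(mean((window - m)^2)),
    range = max(window) - min(window))
}

# vectorized over all windows of one axis: T x width matrix -> T x 3
window_stats_matrix <- function(w) {
  m <- rowMeans(w)
  cbind(mean = m,
        sd = sqrt(pmax(rowMeans((w - m)^2), 0)),  # population SD, divisor n
        range = apply(w, 1L, max) - apply(w, 1L, min))
}

# unscaled T x 13 feature matrix for one trial
raw_features <- function(trial, windows = NULL, width = 6L) {
  if (is.null(windows)) windows <- make_windows(trial$acc_v, trial$acc_ap, width)
  sv <- window_stats_matrix(windows$v)
  sap <- window_stats_matrix(windows$ap)
  n <- nrow(sv)
  m <- trial$meta
  x <- cbind(sv[, "mean"], sv[, "sd"], sv[, "range"],
             sap[, "mean"], sap[, "sd"], sap[, "range"],
             rep(m$mass, n), rep(m$height, n), rep(m$speed, n),
             rep(m$slope, n), rep(m$fs_rear, n), rep(m$fs_mid, n),
             rep(m$fs_fore, n))
  colnames(x) <- FEATURE_NAMES
  x
}

#' Fit min-max normalization parameters on training trials
#'
#' Computes per-feature minima and maxima over the pooled frames of the
#' training trials only, so that scaling a training feature to `[0, 1]`
#' never leaks information from test subjects. Degenerate features with
#' `min == max` are later mapped to 0; test-set values outside the training
#' range scale beyond `[0, 1]` and are deliberately not clipped.
#'
#' @param feature_list List of unscaled `T x 13` feature matrices (one per
#'   training trial), as produced internally by [build_features()] with
#'   `params = NULL`, or via `raw = TRUE`.
#' @return A `norm_params` object with `min`, `max`, and feature names.
#' @export
fit_normalization <- function(feature_list) {
  if (length(feature_list) < 1L) stop("fit_normalization: empty training set")
  pooled <- do.call(rbind, feature_list)
  structure(list(min = apply(pooled, 2L, min),
                 max = apply(pooled, 2L, max),
                 features = colnames(pooled)),
            class = "norm_params")
}

apply_normalization <- function(x, params) {
  if (!identical(colnames(x), params$features))
    stop("feature names do not match normalization params: expected [",
         paste(params$features, collapse = ", "), "], got [",
         paste(colnames(x), collapse = ", "), "]")
  span <- params$max - params$min
  out <- sweep(x, 2L, params$min, `-`)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], `/`)
  out[, !nz] <- 0
  out
}

#' Build the scaled per-frame feature sequence for one trial
#'
#' Assembles the 13-column feature matrix of the model input: the mean, SD
#' and range of each 6-frame acceleration window (both axes) plus the
#' trial's static descriptors (mass, height, speed, slope, and the three
#' foot-strike percentages) broadcast across frames, all min-max scaled
#' with training-set parameters.
#'
#' @param trial A preprocessed `gait_trial`.
#' @param windows Optional [make_windows()] result (recomputed if `NULL`).
#' @param params A `norm_params` from [fit_normalization()], or `NULL` to
#'   return the unscaled matrix.
#' @return A `T x 13` numeric matrix with feature names as column names and
#'   the normalization parameters attached as attribute `"norm_params"`.
#' @export
build_features <- function(trial, windows = NULL, params = NULL) {
  x <- raw_features(trial, windows)
  if (!is.null(params)) {
    x <- apply_normalization(x, params)
    attr(x, "norm_params") <- params
  }
  x
}

#' Drop the foot-strike pattern columns (single-accelerometer ablation)
#'
#' Removes `fs_rear`, `fs_mid`, `fs_fore`, leaving the 10 features
#' available from the sacral accelerometer alone, preserving order.
#'
#' @param seq A feature matrix containing the three foot-strike columns.
#' @return The 10-column matrix.
#' @export
drop_footstrike <- function(seq) {
  fs <- c("fs_rear", "fs_mid", "fs_fore")
  if (!all(fs %in% colnames(seq)))
    stop("drop_footstrike: foot-strike columns already absent")
  seq[, setdiff(colnames(seq), fs), drop = FALSE]
}
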