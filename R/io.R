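#' Write a trial to CSV (plus a metadata sidecar)
#'
#' CSV columns: `time_s`, `grf_BW` (omitted when the trial carries no
#' GRF), `acc_v`, `acc_ap`; unit documentation rides in `#` comment lines.
#' Trial metadata goes to `<path without .csv>.meta.json`.
#'
#' @param trial A `gait_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  n <- length(trial$acc_v)
  df <- data.frame(time_s = (seq_len(n) - 1) / trial$acc_v$rate)
  if (!is.null(trial$grf)) df$grf_BW <- trial$grf$samples
  df$acc_v <- trial$acc_v$samples
  df$acc_ap <- trial$acc_ap$samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# grfcast trial file",
               "# time_s [s]; grf_BW [bodyweights]; acc_v, acc_ap [m/s^2]"),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  meta_path <- sub("\\.csv$", ".meta.json", path)
  jsonlite::write_json(unclass(trial$meta), meta_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial from CSV
#'
#' Inverse of [write_trial()]: validates the schema, infers the sampling
#' rate from the time column (which must be uniform to within 1e-6 s), and
#' loads the metadata sidecar when present. A file without `grf_BW` yields
#' a trial valid for prediction only.
#'
#' @param path CSV path.
#' @return A `gait_trial` (with `grf = NULL` if absent).
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("read_trial: no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!"time_s" %in% names(df)) stop("read_trial: missing column time_s")
  for (col in c("acc_v", "acc_ap"))
    if (!col %in% names(df)) stop("read_trial: missing column ", col)
  t <- df$time_s
  if (length(t) < 2L) stop("read_trial: need at least 2 samples")
  dt <- diff(t)
  bad <- which(abs(dt - dt[1]) > 1e-6)
  if (length(bad))
    stop(sprintf("read_trial: non-uniform sampling at row %d (dt %g vs %g)",
                 bad[1] + 1L, dt[bad[1]], dt[1]))
  rate <- 1 / dt[1]
  meta_path <- sub("\\.csv$", ".meta.json", path)
  meta <- NULL
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta <- trial_meta(m$subject_id, m$mass, m$height, m$speed, m$slope,
                       m$fs_rear, m$fs_mid, m$fs_fore,
                       step_freq_condition = m$step_freq_condition)
  }
  grf <- if ("grf_BW" %in% names(df))
    signal_trace(df$grf_BW, rate, "grf_normal_BW", "BW") else NULL
  structure(list(meta = meta, grf = grf,
                 acc_v = signal_trace(df$acc_v, rate, "acc_vertical", "m/s^2"),
                 acc_ap = signal_trace(df$acc_ap, rate,
                                       "acc_anteroposterior", "m/s^2"),
                 truth = NULL, tilt_deg = NA_real_),
            class = "gait_trial")
}

#' Write a simulated cohort to a directory
#'
#' One CSV (plus metadata sidecar) per trial, a `cohort.csv` listing all
#' trials, and a `truth.csv` with the simulator's per-step ground truth.
#'
#' @param trials List of `gait_trial`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_rows <- list(); truth_rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fname <- sprintf("trial_%03d.csv", i)
    write_trial(tr, file.path(dir, fname))
    meta_rows[[i]] <- cbind(data.frame(file = fname),
                            as.data.frame(unclass(tr$meta)))
    if (!is.null(tr$truth))
      truth_rows[[i]] <- cbind(data.frame(file = fname,
                                          step_freq = tr$truth$step_freq),
                               tr$truth$steps)
  }
  utils::write.csv(do.call(rbind, meta_rows), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  if (length(truth_rows))
    utils::write.csv(do.call(rbind, truth_rows), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv` and trial files.
#' @return List of `gait_trial`s.
#' @export
read_cohort <- function(dir) {
  idx_path <- file.path(dir, "cohort.csv")
  if (!file.exists(idx_path)) stop("read_cohort: no cohort.csv in ", dir)
  idx <- utils::read.csv(idx_path)
  lapply(idx$file, function(f) read_trial(file.path(dir, f)))
}

default_run_config <- function() {
  list(
    seed = 1L,
    sim = list(slopes = c(-10, -5, 0, 5, 10), speeds = c(2.5, 3.33, 4.17),
               sf_conditions = c("+10%", "-10%"), sf_speed = 3.33,
               n_subjects = 19L, duration = 5, rate = 2000,
               noise_sd = 0.5, ring_amp = 3, ring_freq = 25, ring_tau = 0.03,
               tilt_sd = 3, seed = 1L),
    preprocess = list(rate_hz = 500, grf_cutoff_hz = 30, acc_cutoff_hz = 20,
                      window_frames = 6L),
    features = list(drop_footstrike = FALSE),
    model = list(lstm_units = 128L, mlp_sizes = c(128L, 384L, 320L),
                 input_dropout = 0.20, post_lstm_dropout = 0.40),
    train = list(batch_size = 32L, learning_rate = 0.001,
                 max_epochs = 1000L, min_delta = 0.001, patience = 30L,
                 truncate_to = NULL),
    evaluate = list(threshold = 0.05, max_step_freq = 4, debounce = TRUE)
  )
}

#' Read a YAML run configuration
#'
#' Merges the user's YAML over the package defaults (which equal the
#' published pipeline values) and rejects unknown sections or keys.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A nested `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("read_run_config: unknown section(s): ", paste(bad, collapse = ", "))
    for (sec in names(user)) {
      if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
      badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badk))
        stop(sprintf("read_run_config: unknown key(s) in %s: %s", sec,
                     paste(badk, collapse = ", ")))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a config snapshot into an output directory
#'
#' @param cfg A `run_config`.
#' @param dir Target directory.
#' @return The snapshot path, invisibly.
#' @export
write_config_snapshot <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "config_snapshot.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_config_model <- function(cfg, seed = cfg$seed) {
  model_config(lstm_units = cfg$model$lstm_units,
               mlp_sizes = cfg$model$mlp_sizes,
               input_dropout = cfg$model$input_dropout,
               post_lstm_dropout = cfg$model$post_lstm_dropout,
               batch_size = cfg$train$batch_size,
               learning_rate = cfg$train$learning_rate,
               max_epochs = cfg$train$max_epochs,
               min_delta = cfg$train$min_delta,
               patience = cfg$train$patience,
               seed = seed)
}

run_config_sim <- function(cfg, seed = cfg$sim$seed) {
  s <- cfg$sim
  sim_config(slopes = s$slopes, speeds = s$speeds,
             sf_conditions = s$sf_conditions, sf_speed = s$sf_speed,
             n_subjects = s$n_subjects, duration = s$duration,
             rate = s$rate, noise_sd = s$noise_sd, ring_amp = s$ring_amp,
             ring_freq = s$ring_freq, ring_tau = s$ring_tau,
             tilt_sd = s$tilt_sd, seed = seed)
}
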