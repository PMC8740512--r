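#' Root mean square error between two waveforms
#'
#' Computed over the full waveform (stance and aerial phases alike).
#'
#' @param pred,meas [signal_trace()]s or numeric vectors of equal length.
#' @return RMSE in BW.
#' @export
rmse <- function(pred, meas) {
  p <- if (is_signal_trace(pred)) pred$samples else as.numeric(pred)
  m <- if (is_signal_trace(meas)) meas$samples else as.numeric(meas)
  if (length(p) != length(m))
    stop(sprintf("rmse: length mismatch (%d vs %d)", length(p), length(m)))
  sqrt(mean((p - m)^2))
}

#' Relative RMSE
#'
#' RMSE normalized to the average range of the two compared waveforms,
#' expressed in percent:
#' `rRMSE = RMSE / (0.5 * (range(pred) + range(meas))) * 100`.
#'
#' @inheritParams rmse
#' @return rRMSE in percent.
#' @export
rrmse <- function(pred, meas) {
  p <- if (is_signal_trace(pred)) pred$samples else as.numeric(pred)
  m <- if (is_signal_trace(meas)) meas$samples else as.numeric(meas)
  denom <- 0.5 * ((max(p) - min(p)) + (max(m) - min(m)))
  if (denom == 0) stop("rrmse: both waveforms have zero range")
  rmse(p, m) / denom * 100
}

KINETIC_VARS <- c("step_freq", "contact_time", "impulse", "active_peak",
                  "loading_rate")

# per-trial aggregation of a step_kinetics object: one value per variable
trial_variables <- function(kin) {
  stopifnot(inherits(kin, "step_kinetics"))
  s <- kin$steps
  c(step_freq = kin$step_freq,
    contact_time = mean(s$contact_time),
    impulse = mean(s$impulse),
    active_peak = mean(s$active_peak),
    loading_rate = if (all(is.na(s$loading_rate))) NA_real_
                   else mean(s$loading_rate, na.rm = TRUE))
}

#' Mean absolute percent error of the discrete variables
#'
#' Compares trial-aggregated variables computed from predicted and
#' measured waveforms of the same trials: per trial,
#' `|pred - meas| / |meas| * 100`; trials whose measured value is zero (or
#' undefined) are excluded with a flag.
#'
#' @param pred_vars,meas_vars Data frames (or single rows) of per-trial
#'   variables as produced by [trial_variables()], one row per trial,
#'   columns `step_freq`, `contact_time`, `impulse`, `active_peak`,
#'   `loading_rate`.
#' @return Named vector of per-variable MAPE (%), with attribute
#'   `n_excluded` counting skipped trial-variable pairs.
#' @export
mape <- function(pred_vars, meas_vars) {
  pred_vars <- as.data.frame(rbind(pred_vars))
  meas_vars <- as.data.frame(rbind(meas_vars))
  stopifnot(nrow(pred_vars) == nrow(meas_vars))
  excluded <- 0L
  out <- vapply(KINETIC_VARS, function(v) {
    p <- pred_vars[[v]]; m <- meas_vars[[v]]
    ok <- is.finite(p) & is.finite(m) & m != 0
    excluded <<- excluded + sum(!ok)
    if (!any(ok)) return(NA_real_)
    mean(abs(p[ok] - m[ok]) / abs(m[ok]) * 100)
  }, numeric(1))
  attr(out, "n_excluded") <- excluded
  out
}

# preprocess + raw features + targets for a list of trials
prepare_trials <- function(trials, rate = 500, grf_cutoff_hz = 30,
                           acc_cutoff_hz = 20) {
  proc <- lapply(trials, preprocess_trial, rate = rate,
                 grf_cutoff_hz = grf_cutoff_hz, acc_cutoff_hz = acc_cutoff_hz)
  raw <- lapply(proc, raw_features)
  targets <- lapply(proc, function(tr) tr$grf$samples)
  list(proc = proc, raw = raw, targets = targets)
}

trial_label <- function(tr) {
  sprintf("%s|%.2f|%+g|%s", tr$meta$subject_id, tr$meta$speed,
          tr$meta$slope, tr$meta$step_freq_condition)
}

# train on one fold: fit normalization on the training trials only
fit_fold <- function(prep, train_idx, cfg, drop_fs = FALSE, seed = cfg$seed,
                     truncate_to = NULL) {
  raw_train <- prep$raw[train_idx]
  if (drop_fs) raw_train <- lapply(raw_train, drop_footstrike)
  params <- fit_normalization(raw_train)
  feats <- lapply(raw_train, apply_normalization, params = params)
  targ <- prep$targets[train_idx]
  if (!is.null(truncate_to)) {
    feats <- lapply(feats, function(x) x[seq_len(truncate_to), , drop = FALSE])
    targ <- lapply(targ, function(y) y[seq_len(truncate_to)])
  }
  cfg$seed <- as.integer(seed)
  model <- grf_build(cfg, feature_names = colnames(feats[[1]]))
  grf_train(model, feats, targ, norm_params = params)
}

# predict + score the test trials of one fold
score_fold <- function(prep, test_idx, model, drop_fs = FALSE,
                       threshold = 0.05, max_step_freq = 4,
                       truncate_to = NULL, rate = 500, ...) {
  params <- model$norm_params
  rows <- list()
  for (i in test_idx) {
    raw <- prep$raw[[i]]
    if (drop_fs) raw <- drop_footstrike(raw)
    feats <- apply_normalization(raw, params)
    y <- prep$targets[[i]]
    if (!is.null(truncate_to)) {
      feats <- feats[seq_len(truncate_to), , drop = FALSE]
      y <- y[seq_len(truncate_to)]
    }
    pred <- grf_predict(model, feats, rate = rate)
    meas <- signal_trace(y, rate, "grf_normal_BW", "BW")
    verdict <- check_boundaries(pred, meas, max_step_freq = max_step_freq,
                                threshold = threshold, ...)
    pv <- trial_variables(discrete_variables(
      pred, segment_stance(pred, threshold, ...)))
    mv <- trial_variables(discrete_variables(
      meas, segment_stance(meas, threshold, ...)))
    meta <- prep$proc[[i]]$meta
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(trial = trial_label(prep$proc[[i]]),
                 subject = meta$subject_id, speed = meta$speed,
                 slope = meta$slope, sf_condition = meta$step_freq_condition,
                 rmse = rmse(pred, meas), rrmse = rrmse(pred, meas),
                 contact_count_ok = verdict$contact_count_ok,
                 step_freq_ok = verdict$step_freq_ok,
                 passed = verdict$passed),
      as.data.frame(rbind(stats::setNames(pv, paste0("pred_", names(pv))))),
      as.data.frame(rbind(stats::setNames(mv, paste0("meas_", names(mv))))))
  }
  do.call(rbind, rows)
}

# assemble per-subject and grand summaries; failed trials excluded from
# metric aggregates but counted in the failure rate
build_report <- function(per_trial, folds = NULL) {
  ok <- per_trial[per_trial$passed, , drop = FALSE]
  mape_cols <- paste0("mape_", KINETIC_VARS)
  if (nrow(ok) == 0L) {
    # every trial failed the boundary checks: no metric aggregates exist
    per_subject <- cbind(
      data.frame(subject = character(0), n_trials = integer(0),
                 rmse = numeric(0), rmse_sd = numeric(0),
                 rrmse = numeric(0), rrmse_sd = numeric(0)),
      stats::setNames(as.data.frame(matrix(numeric(0), 0, length(mape_cols))),
                      mape_cols))
  } else {
  per_subject <- do.call(rbind, lapply(split(ok, ok$subject), function(d) {
    pv <- d[, paste0("pred_", KINETIC_VARS)]
    mv <- d[, paste0("meas_", KINETIC_VARS)]
    names(pv) <- KINETIC_VARS; names(mv) <- KINETIC_VARS
    mp <- mape(pv, mv)
    cbind(data.frame(subject = d$subject[1], n_trials = nrow(d),
                     rmse = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
                     rrmse = mean(d$rrmse), rrmse_sd = stats::sd(d$rrmse)),
          as.data.frame(rbind(stats::setNames(mp, paste0("mape_", names(mp))))))
  }))
  }
  rownames(per_subject) <- NULL
  n_total <- nrow(per_trial)
  n_contact_fail <- sum(!per_trial$contact_count_ok)
  n_sf_only <- sum(per_trial$contact_count_ok & !per_trial$step_freq_ok)
  n_failed <- sum(!per_trial$passed)
  empty <- nrow(per_subject) == 0L
  structure(list(
    per_trial = per_trial,
    per_subject = per_subject,
    grand = if (empty) list(rmse = NA_real_, rmse_sd = NA_real_,
                            rrmse = NA_real_, rrmse_sd = NA_real_)
            else list(rmse = mean(per_subject$rmse),
                      rmse_sd = stats::sd(per_subject$rmse),
                      rrmse = mean(per_subject$rrmse),
                      rrmse_sd = stats::sd(per_subject$rrmse)),
    mape = if (empty) stats::setNames(rep(NA_real_, length(mape_cols)),
                                      mape_cols)
           else colMeans(as.matrix(per_subject[, mape_cols, drop = FALSE]),
                         na.rm = TRUE),
    failure = list(n_total = n_total, n_failed = n_failed,
                   n_contact_fail = n_contact_fail, n_sf_only = n_sf_only,
                   rate = n_failed / n_total),
    folds = folds), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d trials, %d/%d subjects with metrics | RMSE %.3f +/- %.3f BW | rRMSE %.2f +/- %.2f %% | failure rate %.1f%%\n",
    x$failure$n_total, nrow(x$per_subject),
    length(unique(x$per_trial$subject)),
    x$grand$rmse, x$grand$rmse_sd, x$grand$rrmse, x$grand$rrmse_sd,
    100 * x$failure$rate))
  mp <- x$mape
  cat("  MAPE [%]:", paste(sprintf("%s %.2f", sub("mape_", "", names(mp)), mp),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the tested subject's trials are withheld, the
#' network is trained on everyone else, and min-max normalization is
#' fitted on the fold's training frames only (leak-free). Per-trial
#' waveform errors, per-subject means, discrete-variable MAPE, boundary
#' verdicts and the cohort failure rate are pooled into one report.
#'
#' @param trials List of `gait_trial`s with measured GRF.
#' @param model_cfg A [model_config()].
#' @param drop_fs Train without the foot-strike features (ablation mode)?
#' @param rate,grf_cutoff_hz,acc_cutoff_hz Preprocessing parameters.
#' @param truncate_to Optional frame count for desk-scale runs (sequences
#'   are cut to the first `truncate_to` frames; documented deviation).
#' @param threshold,max_step_freq Boundary-check parameters.
#' @param verbose Print fold progress?
#' @return An `eval_report`.
#' @export
loso <- function(trials, model_cfg = model_config(), drop_fs = FALSE,
                 rate = 500, grf_cutoff_hz = 30, acc_cutoff_hz = 20,
                 truncate_to = NULL, threshold = 0.05, max_step_freq = 4,
                 verbose = FALSE) {
  subjects <- vapply(trials, function(tr) tr$meta$subject_id, character(1))
  if (length(unique(subjects)) < 2L) stop("loso: need at least 2 subjects")
  if (any(table(subjects) == 0L)) stop("loso: subject with zero trials")
  prep <- prepare_trials(trials, rate, grf_cutoff_hz, acc_cutoff_hz)
  per_trial <- list()
  folds <- list()
  for (fold in seq_along(unique(subjects))) {
    s <- unique(subjects)[fold]
    test_idx <- which(subjects == s)
    train_idx <- which(subjects != s)
    if (verbose) message(sprintf("LOSO fold %d: testing %s", fold, s))
    model <- fit_fold(prep, train_idx, model_cfg, drop_fs,
                      seed = model_cfg$seed + fold, truncate_to = truncate_to)
    per_trial[[fold]] <- score_fold(prep, test_idx, model, drop_fs,
                                    threshold, max_step_freq,
                                    truncate_to, rate)
    folds[[s]] <- list(test = test_idx, train = train_idx,
                       epochs = model$epochs,
                       norm_params = model$norm_params)
  }
  build_report(do.call(rbind, per_trial), folds)
}

#' Single-subject slope-split validation
#'
#' Trains on one subject's 0 and +/-10 degree trials and tests on the
#' +/-5 degree trials, probing interpolation to speed-slope combinations
#' absent from training.
#'
#' @param trials Trials of a single subject covering all five slopes.
#' @inheritParams loso
#' @return An `eval_report` (test trials are the +/-5 degree conditions).
#' @export
slope_split <- function(trials, model_cfg = model_config(), drop_fs = FALSE,
                        rate = 500, grf_cutoff_hz = 30, acc_cutoff_hz = 20,
                        truncate_to = NULL, threshold = 0.05,
                        max_step_freq = 4) {
  subjects <- unique(vapply(trials, function(tr) tr$meta$subject_id,
                            character(1)))
  if (length(subjects) != 1L)
    stop("slope_split: expected trials from exactly one subject")
  slopes <- vapply(trials, function(tr) tr$meta$slope, numeric(1))
  needed <- c(-10, -5, 0, 5, 10)
  if (!all(needed %in% slopes))
    stop("slope_split: missing slope condition(s): ",
         paste(setdiff(needed, slopes), collapse = ", "))
  prep <- prepare_trials(trials, rate, grf_cutoff_hz, acc_cutoff_hz)
  test_idx <- which(abs(slopes) == 5)
  train_idx <- which(abs(slopes) != 5)
  model <- fit_fold(prep, train_idx, model_cfg, drop_fs,
                    truncate_to = truncate_to)
  per_trial <- score_fold(prep, test_idx, model, drop_fs, threshold,
                          max_step_freq, truncate_to, rate)
  build_report(per_trial,
               folds = list(split = list(test = test_idx, train = train_idx,
                                         epochs = model$epochs)))
}

#' Canonical feature grouping for permutation importance
#'
#' Groups the 13 features into the seven factors typically reported:
#' vertical acceleration (mean/SD/range), anteroposterior acceleration,
#' foot-strike pattern (three percentages), slope, speed, height, mass.
#'
#' @return Named list of feature-name vectors.
#' @export
pfi_groups <- function() {
  list(vertical_acceleration = c("mean_v", "sd_v", "range_v"),
       anteroposterior_acceleration = c("mean_ap", "sd_ap", "range_ap"),
       foot_strike = c("fs_rear", "fs_mid", "fs_fore"),
       slope = "slope", speed = "speed", height = "height",
       body_mass = "mass")
}

#' Permutation feature importance
#'
#' For each feature (or feature group) the whole-trial feature content is
#' shuffled across trials, severing the learned link between that feature
#' and the GRF waveform while preserving within-trial temporal structure;
#' predictions are recomputed and PFI is the mean over permutations of
#' (permuted pooled RMSE) / (baseline pooled RMSE).
#'
#' @param model A trained `grf_model`.
#' @param features List of scaled `T x F` feature matrices (>= 2 trials).
#' @param targets List of measured GRF vectors (BW) matching `features`.
#' @param n_perm Number of permutations per feature (default 100).
#' @param groups Named list mapping importance names to feature-name
#'   vectors; defaults to each feature on its own.
#' @param seed RNG seed.
#' @param perms Optional list of explicit permutation vectors (overrides
#'   `n_perm`; mainly for testing, e.g. the identity permutation).
#' @return A `pfi_result`: data frame with `feature` and `pfi` columns,
#'   plus baseline RMSE, permutation count and seed as attributes.
#' @export
permutation_importance <- function(model, features, targets, n_perm = 100L,
                                   groups = NULL, seed = 1L, perms = NULL) {
  n <- length(features)
  if (n < 2L) stop("permutation_importance: need at least 2 trials")
  stopifnot(length(targets) == n)
  nm <- colnames(features[[1]])
  if (is.null(groups)) groups <- stats::setNames(as.list(nm), nm)
  pooled_rmse <- function(feat_list) {
    preds <- grf_predict(model, feat_list)
    sq <- unlist(Map(function(p, y) (p$samples - y)^2, preds, targets))
    sqrt(mean(sq))
  }
  baseline <- pooled_rmse(features)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(perms))
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  res <- vapply(names(groups), function(gname) {
    cols <- groups[[gname]]
    if (!all(cols %in% nm))
      stop("permutation_importance: unknown feature(s): ",
           paste(setdiff(cols, nm), collapse = ", "))
    ratios <- vapply(perms, function(pm) {
      permuted <- features
      for (i in seq_len(n))
        permuted[[i]][, cols] <- features[[pm[i]]][, cols]
      pooled_rmse(permuted) / baseline
    }, numeric(1))
    mean(ratios)
  }, numeric(1))
  structure(data.frame(feature = names(groups), pfi = unname(res)),
            baseline_rmse = baseline, n_perm = length(perms), seed = seed,
            class = c("pfi_result", "data.frame"))
}
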