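GRAVITY <- 9.81

#' Per-trial static descriptors
#'
#' Metadata accompanying every trial: who ran, how heavy/tall they are, and
#' the treadmill condition (speed, slope, step-frequency condition) plus the
#' foot-strike composition of the trial's steps.
#'
#' @param subject_id Opaque subject label.
#' @param mass Body mass in kg (> 0).
#' @param height Height in cm (> 0).
#' @param speed Belt speed in m/s (> 0).
#' @param slope Signed slope in degrees, positive uphill.
#' @param fs_rear,fs_mid,fs_fore Percentage of the trial's steps classified
#'   as rearfoot / midfoot / forefoot strikes; must sum to 100.
#' @param step_freq_condition `"preferred"`, `"+10%"` or `"-10%"`.
#' @param slope_range Declared training envelope for the slope check.
#' @return A `trial_meta` object.
#' @export
trial_meta <- function(subject_id, mass, height, speed, slope,
                       fs_rear = 100, fs_mid = 0, fs_fore = 0,
                       step_freq_condition = c("preferred", "+10%", "-10%"),
                       slope_range = c(-10, 10)) {
  step_freq_condition <- match.arg(step_freq_condition)
  stopifnot(mass > 0, height > 0, speed > 0)
  if (abs(fs_rear + fs_mid + fs_fore - 100) > 1e-9)
    stop("trial_meta: foot-strike percentages must sum to 100")
  if (slope < slope_range[1] || slope > slope_range[2])
    stop(sprintf("trial_meta: slope %g outside training envelope [%g, %g]",
                 slope, slope_range[1], slope_range[2]))
  structure(list(subject_id = as.character(subject_id), mass = mass,
                 height = height, speed = speed, slope = slope,
                 fs_rear = fs_rear, fs_mid = fs_mid, fs_fore = fs_fore,
                 step_freq_condition = step_freq_condition),
            class = "trial_meta")
}

#' Simulator configuration
#'
#' Declares the condition grid and noise model of the synthetic cohort. The
#' defaults mirror the acquisition that the pipeline expects: 5 s trials
#' sampled at 2,000 Hz over five slopes (0, +/-5, +/-10 degrees), three
#' speeds (2.5, 3.33, 4.17 m/s), and +/-10% step-frequency conditions at
#' 3.33 m/s.
#'
#' @param slopes Slopes (degrees) in the condition grid.
#' @param speeds Speeds (m/s) in the condition grid.
#' @param sf_conditions Step-frequency conditions added at `sf_speed`.
#' @param sf_speed Speed (m/s) at which the +/-10% conditions are run.
#' @param n_subjects Number of subjects.
#' @param duration Trial duration in s.
#' @param rate Raw sampling rate in Hz.
#' @param noise_sd Accelerometer white-noise SD, m/s^2.
#' @param ring_amp Soft-tissue ringing amplitude at impact, m/s^2.
#' @param ring_freq Ringing frequency, Hz.
#' @param ring_tau Ringing exponential decay time constant, s.
#' @param tilt_sd Per-subject sensor mis-orientation SD, degrees.
#' @param seed RNG seed fixing all randomness.
#' @return A `sim_config` object.
#' @export
sim_config <- function(slopes = c(-10, -5, 0, 5, 10),
                       speeds = c(2.5, 3.33, 4.17),
                       sf_conditions = c("+10%", "-10%"),
                       sf_speed = 3.33,
                       n_subjects = 19L,
                       duration = 5,
                       rate = 2000,
                       noise_sd = 0.5,
                       ring_amp = 3,
                       ring_freq = 25,
                       ring_tau = 0.03,
                       tilt_sd = 3,
                       seed = 1L) {
  stopifnot(duration > 0, rate > 0, n_subjects >= 1, noise_sd >= 0,
            ring_amp >= 0, ring_freq > 0, ring_tau > 0, tilt_sd >= 0)
  structure(list(slopes = slopes, speeds = speeds,
                 sf_conditions = sf_conditions, sf_speed = sf_speed,
                 n_subjects = as.integer(n_subjects), duration = duration,
                 rate = rate, noise_sd = noise_sd, ring_amp = ring_amp,
                 ring_freq = ring_freq, ring_tau = ring_tau,
                 tilt_sd = tilt_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Step-frequency model: increases mildly with speed and with uphill slope
# (runners shorten steps uphill), scaled by the step-frequency condition.
base_step_freq <- function(speed, slope, step_freq_condition = "preferred",
                           subject_shift = 0) {
  f <- 2.75 + 0.105 * speed + 0.015 * slope + subject_shift
  mult <- switch(step_freq_condition, "preferred" = 1, "+10%" = 1.1,
                 "-10%" = 0.9)
  f * mult
}

# Duty factor (contact time / step period): shortens with speed.
duty_factor <- function(speed) 0.70 - 0.02 * speed

# Impact-bump amplitude in BW: grows with downhill slope and the rearfoot
# fraction, zero for sufficiently uphill slopes.
impact_amplitude <- function(slope, fs_rear) {
  (fs_rear / 100) * max(0, 0.25 - 0.04 * slope)
}

# Parameters shared by every step of one trial. The active amplitude A is
# chosen so the whole-step impulse equals cos(slope) * period exactly
# (stance-aerial force balance), after accounting for the impact bump.
trial_step_params <- function(meta, subject_shift = 0) {
  f_step <- base_step_freq(meta$speed, meta$slope, meta$step_freq_condition,
                           subject_shift)
  period <- 1 / f_step
  tc <- duty_factor(meta$speed) * period
  amp_imp <- impact_amplitude(meta$slope, meta$fs_rear)
  t_peak <- 0.15 * tc
  sigma <- 0.05 * tc
  # impulse of the truncated Gaussian bump over [0, tc]
  bump_impulse <- amp_imp * sigma * sqrt(2 * pi) *
    (stats::pnorm((tc - t_peak) / sigma) - stats::pnorm(-t_peak / sigma))
  ctheta <- cos(meta$slope * pi / 180)
  A <- (ctheta * period - bump_impulse) * pi / (2 * tc)
  list(f_step = f_step, period = period, tc = tc, A = A,
       amp_imp = amp_imp, t_peak = t_peak, sigma = sigma)
}

# Normal GRF (BW) of one step evaluated at times t in [0, period):
# half-sine active component plus a Gaussian impact bump in early stance.
step_grf_at <- function(t, p) {
  f <- ifelse(t >= 0 & t <= p$tc, p$A * sin(pi * pmin(pmax(t, 0), p$tc) / p$tc), 0)
  if (p$amp_imp > 0)
    f <- f + ifelse(t >= 0 & t <= p$tc,
                    p$amp_imp * exp(-0.5 * ((t - p$t_peak) / p$sigma)^2), 0)
  f
}

#' Simulate one step's normal GRF waveform
#'
#' One step period of normal GRF in bodyweights: a half-sine active
#' component `A * sin(pi * t / tc)` during stance, zero during the aerial
#' phase, plus an additive early-stance impact bump whose amplitude grows
#' with downhill slope and the rearfoot-strike fraction.
#'
#' @param meta A [trial_meta()].
#' @param A Active amplitude in BW; default derived from `meta` by force
#'   balance.
#' @param tc Contact time in s; default from the duty-factor model.
#' @param rate Sampling rate in Hz.
#' @return A `signal_trace` covering one step period.
#' @export
simulate_step_grf <- function(meta, A = NULL, tc = NULL, rate = 2000) {
  stopifnot(rate > 0)
  p <- trial_step_params(meta)
  if (!is.null(A)) p$A <- A
  if (!is.null(tc)) {
    if (tc >= p$period)
      stop("simulate_step_grf: tc must be shorter than the step period (no aerial phase)")
    p$tc <- tc
  }
  t <- seq(0, p$period - 1 / rate, by = 1 / rate)
  signal_trace(step_grf_at(t, p), rate, axis = "grf_normal_BW", units = "BW")
}

# duration (s) the step waveform stays above `thr` BW, solved numerically
supra_threshold_duration <- function(p, thr = 0.05) {
  f <- function(t) step_grf_at(t, p) - thr
  if (step_grf_at(p$tc / 2, p) <= thr) return(0)
  t_on <- stats::uniroot(f, c(0, p$tc / 2), tol = 1e-10)$root
  t_off <- stats::uniroot(f, c(p$tc / 2, p$tc), tol = 1e-10)$root
  t_off - t_on
}

#' Simulate one treadmill trial
#'
#' Builds a `duration x rate` paired GRF/acceleration trial. Steps repeat at
#' the trial's step frequency; vertical acceleration follows whole-body
#' dynamics `a_v = g * (F_BW - cos(slope))` plus impact-synchronous damped
#' ringing and sensor noise; anteroposterior acceleration is a biphasic
#' braking-propulsion wave per stance plus a slope-dependent gravity bias.
#' A small per-subject sensor tilt mixes the two axes. A ground-truth
#' kinetics record is attached for every step.
#'
#' @param meta A [trial_meta()].
#' @param cfg A [sim_config()].
#' @param subject_shift Per-subject step-frequency offset in Hz.
#' @param tilt_deg Sensor mis-orientation in degrees (0 = aligned).
#' @param noise Logical; set `FALSE` for a noiseless, ringing-free trial.
#' @return A `gait_trial`: list with `meta`, `grf`, `acc_v`, `acc_ap`,
#'   `truth`, and the tilt used.
#' @export
simulate_trial <- function(meta, cfg = sim_config(), subject_shift = 0,
                           tilt_deg = 0, noise = TRUE) {
  p <- trial_step_params(meta, subject_shift)
  n <- round(cfg$duration * cfg$rate)
  t <- (seq_len(n) - 1) / cfg$rate
  phase <- t %% p$period
  grf <- step_grf_at(phase, p)

  theta <- meta$slope * pi / 180
  acc_v <- GRAVITY * (grf - cos(theta))

  # anteroposterior: braking then propulsion within stance, plus the
  # along-surface gravity component felt during the aerial phase
  in_stance <- phase <= p$tc
  B <- 1.5 + 0.5 * meta$speed
  acc_ap <- ifelse(in_stance, -B * sin(2 * pi * phase / p$tc), 0) -
    GRAVITY * sin(theta)

  # onsets strictly inside [0, duration); guard seq() fuzz at the boundary
  n_onsets <- ceiling(cfg$duration / p$period - 1e-9)
  onsets <- (seq_len(n_onsets) - 1) * p$period

  if (noise) {
    ring <- numeric(n)
    for (o in onsets) {
      idx <- which(t >= o & t < o + 6 * cfg$ring_tau)
      tau <- t[idx] - o
      ring[idx] <- ring[idx] + cfg$ring_amp * exp(-tau / cfg$ring_tau) *
        sin(2 * pi * cfg$ring_freq * tau)
    }
    acc_v <- acc_v + ring + stats::rnorm(n, 0, cfg$noise_sd)
    acc_ap <- acc_ap + 0.4 * ring + stats::rnorm(n, 0, cfg$noise_sd)
  }

  if (tilt_deg != 0) {
    phi <- tilt_deg * pi / 180
    av <- cos(phi) * acc_v - sin(phi) * acc_ap
    aap <- sin(phi) * acc_v + cos(phi) * acc_ap
    acc_v <- av; acc_ap <- aap
  }

  truth <- list(
    steps = data.frame(
      onset = onsets,
      tc = p$tc,
      contact_dur_5pct = supra_threshold_duration(p, 0.05),
      active_amp = p$A,
      impact_amp = p$amp_imp,
      impact_frac = p$t_peak / p$tc,
      impulse = cos(theta) * p$period,
      # stance fully inside the record? (edge contacts are truncated)
      complete = onsets + p$tc <= cfg$duration + 1e-12
    ),
    step_freq = p$f_step,
    # what a contacts-per-second measurement can see on this finite trial
    step_freq_count = length(onsets) / cfg$duration
  )

  structure(list(
    meta = meta,
    grf = signal_trace(grf, cfg$rate, "grf_normal_BW", "BW"),
    acc_v = signal_trace(acc_v, cfg$rate, "acc_vertical", "m/s^2"),
    acc_ap = signal_trace(acc_ap, cfg$rate, "acc_anteroposterior", "m/s^2"),
    truth = truth, tilt_deg = tilt_deg
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> subject %s | %.2f m/s, %+g deg, %s SF | %d steps, %g Hz\n",
    x$meta$subject_id, x$meta$speed, x$meta$slope,
    x$meta$step_freq_condition, nrow(x$truth$steps), x$grf$rate))
  invisible(x)
}

# condition grid for one subject: slopes x speeds, plus +/-10% SF at sf_speed
condition_grid <- function(cfg) {
  grid <- expand.grid(slope = cfg$slopes, speed = cfg$speeds,
                      sf = "preferred", stringsAsFactors = FALSE)
  if (length(cfg$sf_conditions))
    grid <- rbind(grid, expand.grid(slope = cfg$slopes, speed = cfg$sf_speed,
                                    sf = cfg$sf_conditions,
                                    stringsAsFactors = FALSE))
  grid
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject anthropometrics (mass ~ N(68.1, 9.9) kg, height ~
#' N(173, 9) cm, matching the population the pipeline targets), a
#' foot-strike profile, a step-frequency offset and a sensor tilt once per
#' subject, then simulates every condition in the grid. Deterministic given
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @param noise Logical; passed to [simulate_trial()].
#' @return List of `gait_trial` objects.
#' @export
simulate_cohort <- function(cfg = sim_config(), noise = TRUE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  grid <- condition_grid(cfg)
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    mass <- max(45, stats::rnorm(1, 68.1, 9.9))
    height <- max(150, stats::rnorm(1, 173, 9))
    fs_rear <- min(100, max(0, stats::rnorm(1, 80, 15)))
    fs_mid <- (100 - fs_rear) * stats::runif(1, 0.4, 0.9)
    fs_fore <- 100 - fs_rear - fs_mid
    sf_shift <- stats::rnorm(1, 0, 0.06)
    tilt <- stats::rnorm(1, 0, cfg$tilt_sd)
    for (g in seq_len(nrow(grid))) {
      meta <- trial_meta(sid, mass, height, grid$speed[g], grid$slope[g],
                         fs_rear, fs_mid, fs_fore,
                         step_freq_condition = grid$sf[g])
      trials[[length(trials) + 1L]] <-
        simulate_trial(meta, cfg, subject_shift = sf_shift,
                       tilt_deg = tilt, noise = noise)
    }
  }
  trials
}
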