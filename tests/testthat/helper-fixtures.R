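# Shared fixtures: small metas, cohorts and model configs used across files.

make_meta <- function(subject_id = "S01", mass = 70, height = 175,
                      speed = 3.33, slope = 0, fs_rear = 100, fs_mid = 0,
                      fs_fore = 0, sf = "preferred") {
  trial_meta(subject_id, mass, height, speed, slope, fs_rear, fs_mid,
             fs_fore, step_freq_condition = sf)
}

# a half-sine step train: n_steps contacts of amplitude A and duration tc,
# one per period, sampled at rate
half_sine_train <- function(A = 2.5, tc = 0.22, period = 0.3125,
                            n_steps = 16, rate = 500) {
  t <- seq(0, n_steps * period - 1 / rate, by = 1 / rate)
  phase <- t %% period
  f <- ifelse(phase <= tc, A * sin(pi * phase / tc), 0)
  signal_trace(f, rate, "grf_normal_BW", "BW")
}

# deterministic tiny cohort for pipeline plumbing tests
tiny_cohort <- function(n_subjects = 2, duration = 1.5, noise = TRUE,
                        seed = 42) {
  simulate_cohort(sim_config(
    n_subjects = n_subjects, duration = duration, rate = 1000,
    slopes = c(-10, 0, 10), speeds = c(2.5, 3.33),
    sf_conditions = character(0), seed = seed), noise = noise)
}

# desk-scale model config for plumbing tests (not for accuracy)
tiny_model_config <- function(...) {
  model_config(lstm_units = 8L, mlp_sizes = c(8L, 8L), batch_size = 4L,
               max_epochs = 2L, patience = 2L, input_dropout = 0.2,
               post_lstm_dropout = 0.4, seed = 7L, ...)
}
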