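test_that("segment_stance thresholds a simple pulse", {
  g <- signal_trace(c(0, 0, 0.1, 1, 1, 0.1, 0, 0), 500, "grf_normal_BW")
  seg <- segment_stance(g, debounce = FALSE)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 3L)   # 1-based half-open [3, 7)
  expect_equal(seg$end, 7L)
})

test_that("segment_stance on an empty trace finds zero contacts", {
  g <- signal_trace(rep(0, 100), 500, "grf_normal_BW")
  expect_equal(nrow(segment_stance(g)), 0L)
})

test_that("debounce merges brief aerial gaps and drops blips", {
  rate <- 500
  stance <- rep(1, 100)                   # 200 ms contact
  dip <- stance; dip[50:52] <- 0          # 6 ms dip below threshold
  g <- signal_trace(c(rep(0, 25), dip, rep(0, 50), rep(1, 5), rep(0, 25)),
                    rate, "grf_normal_BW")
  raw <- segment_stance(g, debounce = FALSE)
  expect_equal(nrow(raw), 3L)             # split contact + 10 ms blip
  seg <- segment_stance(g)                # defaults: merge < 10 ms, drop < 25 ms
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end - seg$start, 100L)
})

test_that("contact time on a half-sine train matches the analytic crossing", {
  A <- 2.5; tc <- 0.22; rate <- 500
  g <- half_sine_train(A = A, tc = tc, rate = rate)
  seg <- segment_stance(g, debounce = FALSE)
  kin <- discrete_variables(g, seg)
  # analytic supra-threshold duration: crossings of A sin(pi t / tc) = 0.05
  t_on <- tc / pi * asin(0.05 / A)
  expected_ms <- (tc - 2 * t_on) * 1000
  expect_true(all(abs(kin$steps$contact_time - expected_ms) <= 1000 / rate + 1e-9))
  expect_true(all(abs(kin$steps$contact_time - 220) < 5))
})

test_that("discrete variables recover the analytic half-sine values", {
  A <- 2.5; tc <- 0.22
  g <- half_sine_train(A = A, tc = tc, n_steps = 16, period = 0.3125)
  kin <- discrete_variables(g, segment_stance(g))
  # active peak at 50% stance lies inside the 40-60% window
  expect_equal(kin$steps$active_peak, rep(A, 16), tolerance = 1e-3)
  # impulse: analytic 2 A tc / pi, trapezoid + threshold-tail error
  expect_equal(kin$steps$impulse, rep(2 * A * tc / pi, 16), tolerance = 2e-3)
  # 16 contacts over 5 s
  expect_equal(kin$step_freq, 16 / 5)
})

test_that("loading rate is the exact secant slope of a linear onset ramp", {
  rate <- 500
  f <- c(rep(0, 10), 40 * (0:49) / rate, rep(0, 10))  # 40 BW/s ramp
  g <- signal_trace(f, rate, "grf_normal_BW")
  seg <- segment_stance(g, debounce = FALSE)
  kin <- discrete_variables(g, seg)
  expect_equal(kin$steps$loading_rate, 40, tolerance = 1e-9)
})

test_that("contacts shorter than 25 ms get a flagged, excluded loading rate", {
  g <- signal_trace(c(rep(0, 10), rep(1, 8), rep(0, 10)), 500,
                    "grf_normal_BW")   # 16 ms contact
  kin <- discrete_variables(g, segment_stance(g, debounce = FALSE))
  expect_true(is.na(kin$steps$loading_rate))
  expect_false(is.na(kin$steps$impulse))
})

test_that("impulse is additive over concatenated contacts", {
  g <- half_sine_train(n_steps = 5)
  kin <- discrete_variables(g, segment_stance(g))
  seg <- segment_stance(g)
  total <- sum(vapply(seq_len(nrow(seg)), function(i) {
    x <- g$samples[seg$start[i]:(seg$end[i] - 1)]
    sum((x[-1] + x[-length(x)]) / 2) / g$rate
  }, numeric(1)))
  expect_equal(sum(kin$steps$impulse), total, tolerance = 1e-12)
})

test_that("boundary criteria compare contact counts and cap step frequency", {
  pred16 <- half_sine_train(n_steps = 16, period = 0.3125)   # 3.2 Hz over 5 s
  meas15 <- half_sine_train(n_steps = 15, period = 1 / 3)    # 5 s, 15 contacts
  v <- check_boundaries(pred16, meas15)
  expect_false(v$contact_count_ok)
  expect_false(v$passed)
  # 21 contacts in 5 s -> 4.2 Hz: violates the 4 Hz bound
  fast <- half_sine_train(A = 2, tc = 0.15, n_steps = 21, period = 5 / 21)
  v2 <- check_boundaries(fast)
  expect_equal(v2$step_freq, 4.2)
  expect_false(v2$step_freq_ok)
  # matching counts at 3.2 Hz passes; exactly 4 Hz is inclusive
  v3 <- check_boundaries(pred16, half_sine_train(n_steps = 16, period = 0.3125))
  expect_true(v3$passed)
  at4 <- half_sine_train(A = 2, tc = 0.15, n_steps = 20, period = 0.25)
  expect_true(check_boundaries(at4)$step_freq_ok)
  expect_error(check_boundaries(pred16,
    signal_trace(meas15$samples, 1000, "grf_normal_BW")), "rate")
})

test_that("kinetics on noiseless simulated trials recover generator truth", {
  tr <- simulate_trial(make_meta(slope = -5, speed = 2.5), sim_config(),
                       noise = FALSE)
  kin <- discrete_variables(tr$grf, segment_stance(tr$grf))
  truth <- tr$truth
  expect_equal(nrow(kin$steps), nrow(truth$steps))
  expect_equal(kin$step_freq, truth$step_freq_count, tolerance = 1e-12)
  # a contact truncated by the trial edge carries partial kinetics: compare
  # complete steps only (truth marks them)
  full <- kin$steps[kin$steps$end <= length(tr$grf), ]
  expect_equal(mean(full$active_peak), truth$steps$active_amp[1],
               tolerance = 0.01)
  expect_equal(mean(full$contact_time) / 1000,
               truth$steps$contact_dur_5pct[1], tolerance = 0.01)
  expect_equal(mean(full$impulse), truth$steps$impulse[1],
               tolerance = 0.01)
})
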