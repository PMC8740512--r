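test_that("rmse handles identity, offsets, and random pairs", {
  x <- signal_trace(runif(200), 500, "grf_normal_BW")
  expect_equal(rmse(x, x), 0)
  y <- retraced <- x
  y$samples <- x$samples + 0.1
  expect_equal(rmse(y, x), 0.1, tolerance = 1e-12)
  set.seed(4)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 100), tolerance = 1e-12)
  expect_error(rmse(a, b[1:50]), "length mismatch")
})

test_that("rrmse implements RMSE over the average range, in percent", {
  # constructed: RMSE 0.2, pred range 1, meas range 3 -> 10%
  pred <- c(0, 1, rep(0.5, 98))
  meas <- c(0, 3, rep(0.5, 98))
  expect_equal(rmse(pred, meas), 0.2, tolerance = 1e-12)
  expect_equal(rrmse(pred, meas), 0.2 / (0.5 * (1 + 3)) * 100,
               tolerance = 1e-12)
  # identical nonzero-range traces -> 0%
  expect_equal(rrmse(pred, pred), 0)
  expect_error(rrmse(rep(1, 5), rep(1, 5)), "zero range")
})

test_that("mape compares trial-aggregated variables and flags zeros", {
  v <- data.frame(step_freq = 3.2, contact_time = 210, impulse = 0.33,
                  active_peak = 2.4, loading_rate = 50)
  expect_equal(as.numeric(mape(v, v)), rep(0, 5))
  w <- v; w$contact_time <- 200
  expect_equal(mape(v, w)[["contact_time"]], 5)
  z <- v; z$loading_rate <- 0
  out <- mape(v, z)
  expect_true(is.na(out[["loading_rate"]]))
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("mape matches brute-force recomputation on a random cohort", {
  set.seed(8)
  n <- 20
  pred <- data.frame(step_freq = runif(n, 3, 3.4),
                     contact_time = runif(n, 200, 240),
                     impulse = runif(n, 0.3, 0.36),
                     active_peak = runif(n, 2.2, 2.6),
                     loading_rate = runif(n, 30, 70))
  meas <- pred + matrix(rnorm(n * 5, 0, 0.05), n, 5) * pred
  got <- mape(pred, meas)
  for (v in names(got))
    expect_equal(got[[v]], mean(abs(pred[[v]] - meas[[v]]) / abs(meas[[v]])) * 100,
                 tolerance = 1e-12)
})

test_that("two-subject LOSO swaps roles and never leaks subjects", {
  trials <- tiny_cohort(n_subjects = 2, duration = 1.5, seed = 5)
  rep <- loso(trials, tiny_model_config())
  expect_length(rep$folds, 2L)
  subjects <- vapply(trials, function(tr) tr$meta$subject_id, character(1))
  for (s in names(rep$folds)) {
    fold <- rep$folds[[s]]
    expect_length(intersect(fold$test, fold$train), 0L)
    expect_true(all(subjects[fold$test] == s))
    expect_true(all(subjects[fold$train] != s))
  }
  # every trial tested exactly once
  tested <- sort(unname(unlist(lapply(rep$folds, `[[`, "test"))))
  expect_equal(tested, seq_along(trials))
  expect_equal(nrow(rep$per_trial), length(trials))
})

test_that("loso validates its inputs", {
  trials <- tiny_cohort(n_subjects = 1, duration = 1, seed = 2)
  expect_error(loso(trials, tiny_model_config()), "at least 2 subjects")
})

test_that("slope_split partitions the grid and withholds the test slopes", {
  cfg <- sim_config(n_subjects = 1, duration = 1.5, rate = 1000, seed = 3,
                    sf_conditions = character(0))
  trials <- simulate_cohort(cfg)       # 5 slopes x 3 speeds
  rep <- slope_split(trials, tiny_model_config())
  split <- rep$folds$split
  expect_length(split$test, 6L)        # +/-5 deg x 3 speeds
  expect_length(split$train, 9L)
  slopes <- vapply(trials, function(tr) tr$meta$slope, numeric(1))
  expect_true(all(abs(slopes[split$test]) == 5))
  expect_true(all(abs(slopes[split$train]) %in% c(0, 10)))
  # missing slope condition is an error
  expect_error(slope_split(trials[slopes != 5], tiny_model_config()),
               "missing slope")
  two <- tiny_cohort(n_subjects = 2, duration = 1, seed = 4)
  expect_error(slope_split(two, tiny_model_config()), "one subject")
})

test_that("failure bookkeeping excludes failed trials from aggregates only", {
  # construct a per-trial table directly: 10 trials, 1 contact-count
  # violation, 1 step-frequency violation
  set.seed(6)
  pt <- data.frame(trial = sprintf("t%02d", 1:10),
                   subject = rep(c("A", "B"), each = 5),
                   speed = 3.33, slope = 0, sf_condition = "preferred",
                   rmse = runif(10, 0.05, 0.2), rrmse = runif(10, 3, 8),
                   contact_count_ok = rep(TRUE, 10),
                   step_freq_ok = rep(TRUE, 10))
  pt$contact_count_ok[2] <- FALSE
  pt$step_freq_ok[7] <- FALSE
  pt$passed <- pt$contact_count_ok & pt$step_freq_ok
  for (v in grfcast:::KINETIC_VARS) {
    pt[[paste0("pred_", v)]] <- runif(10, 1, 2)
    pt[[paste0("meas_", v)]] <- runif(10, 1, 2)
  }
  rep <- grfcast:::build_report(pt)
  expect_equal(rep$failure$rate, 0.2)
  expect_equal(rep$failure$n_contact_fail, 1L)
  expect_equal(rep$failure$n_sf_only, 1L)
  # aggregates computed over passing trials only
  ok <- pt[pt$passed, ]
  expect_equal(rep$per_subject$n_trials, c(4L, 4L))
  expect_equal(rep$grand$rmse,
               mean(c(mean(ok$rmse[ok$subject == "A"]),
                      mean(ok$rmse[ok$subject == "B"]))), tolerance = 1e-12)
})

test_that("permutation importance is exactly 1 for identity and constants", {
  task_feats <- lapply(1:4, function(i) {
    x <- matrix(runif(60), 20, 3)
    colnames(x) <- c("mean_v", "mass", "slope")
    x[, "slope"] <- 0.5           # constant across trials
    x
  })
  targets <- lapply(task_feats, function(x) 2 * x[, "mean_v"])
  cfg <- model_config(lstm_units = 4L, mlp_sizes = c(4L), batch_size = 2L,
                      max_epochs = 3L, seed = 1L)
  m <- grf_train(grf_build(cfg, colnames(task_feats[[1]])), task_feats, targets)
  identity_perm <- list(1:4)
  res <- permutation_importance(m, task_feats, targets, perms = identity_perm)
  expect_equal(res$pfi, rep(1, 3))
  # constant feature: any permutation leaves inputs unchanged
  res2 <- permutation_importance(m, task_feats, targets, n_perm = 5, seed = 2)
  expect_equal(res2$pfi[res2$feature == "slope"], 1)
  expect_error(permutation_importance(m, task_feats[1], targets[1]),
               "at least 2")
  expect_error(permutation_importance(m, task_feats, targets, n_perm = 2,
                                      groups = list(bad = "nope")), "unknown")
})
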