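# synthetic sequence task: y_t = 2 * mean_v_t with the remaining columns
# as distractors; linear in one input, so a small network must master it
linear_task <- function(n_trials = 8, T = 80, n_features = 4, seed = 3) {
  set.seed(seed)
  features <- lapply(seq_len(n_trials), function(i) {
    x <- matrix(stats::runif(T * n_features), T, n_features)
    colnames(x) <- c("mean_v", paste0("f", seq_len(n_features - 1)))
    x
  })
  targets <- lapply(features, function(x) 2 * x[, "mean_v"])
  list(features = features, targets = targets)
}

test_that("the network has the published topology", {
  m <- grf_build(model_config(seed = 1))
  expect_length(m$weights$mlp_W, 4L)        # 3 hidden + linear head
  expect_equal(vapply(m$weights$mlp_W, nrow, integer(1)), c(128L, 384L, 320L, 1L))
  expect_equal(nrow(m$weights$Wx_f), 4L * 128L)
  expect_equal(ncol(m$weights$Wx_f), 13L)
  expect_false(m$trained)
})

test_that("output length equals input length for any sequence length", {
  m <- grf_build(tiny_model_config(), feature_names = c("a", "b", "c"))
  for (L in c(1L, 5L, 100L)) {
    x <- matrix(rnorm(L * 3), L, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_length(grf_predict(m, x)$samples, L)
  }
})

test_that("inference is deterministic (dropout inert)", {
  m <- grf_build(tiny_model_config(), feature_names = letters[1:3])
  x <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, letters[1:3]))
  expect_identical(grf_predict(m, x)$samples, grf_predict(m, x)$samples)
})

test_that("analytic gradients match finite differences", {
  w <- grfcast:::nn_init_weights(3L, 4L, c(5L, 4L), 42L)
  set.seed(2)
  X <- replicate(3, matrix(rnorm(15), 5, 3), simplify = FALSE)
  y <- replicate(3, rnorm(5), simplify = FALSE)
  lg <- grfcast:::nn_loss_grad(w, X, y)
  eps <- 1e-6
  bump <- function(w, path, k, e) {
    if (length(path) == 1) w[[path]][k] <- w[[path]][k] + e
    else w[[path[1]]][[as.integer(path[2])]][k] <-
        w[[path[1]]][[as.integer(path[2])]][k] + e
    w
  }
  pick <- function(g, path) if (length(path) == 1) g[[path]]
    else g[[path[1]]][[as.integer(path[2])]]
  paths <- c(as.list(c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b")),
             lapply(1:3, function(i) c("mlp_W", i)),
             lapply(1:3, function(i) c("mlp_b", i)))
  for (pa in paths) {
    g <- pick(lg$grads, pa)
    for (k in sample(length(g), min(5, length(g)))) {
      num <- (grfcast:::nn_loss_grad(bump(w, pa, k, eps), X, y)$loss -
              grfcast:::nn_loss_grad(bump(w, pa, k, -eps), X, y)$loss) / (2 * eps)
      expect_equal(pick(lg$grads, pa)[k], num, tolerance = 1e-4)
    }
  }
})

test_that("a scaled-down network learns a linear map to RMSE < 0.02 BW", {
  task <- linear_task()
  # desk-scale config: a larger step size than the full recipe, verified
  # empirically to master the map within the 200-epoch budget
  cfg <- model_config(lstm_units = 8L, mlp_sizes = c(16L, 16L),
                      input_dropout = 0, post_lstm_dropout = 0,
                      batch_size = 2L, max_epochs = 200L,
                      learning_rate = 0.01,
                      min_delta = 1e-7, patience = 200L, seed = 11L)
  m <- grf_build(cfg, feature_names = colnames(task$features[[1]]))
  m <- grf_train(m, task$features, task$targets)
  preds <- grf_predict(m, task$features)
  train_rmse <- sqrt(mean(unlist(Map(function(p, y) (p$samples - y)^2,
                                     preds, task$targets))))
  expect_lt(train_rmse, 0.02)
  expect_lte(m$epochs, 200L)
})

test_that("early stopping fires on a plateau and records the stop epoch", {
  task <- linear_task(n_trials = 4, T = 30)
  # constant-zero target: loss bottoms out almost immediately
  targets <- lapply(task$targets, function(y) y * 0)
  cfg <- model_config(lstm_units = 4L, mlp_sizes = c(4L),
                      input_dropout = 0, post_lstm_dropout = 0,
                      batch_size = 4L, max_epochs = 500L,
                      min_delta = 0.001, patience = 5L, seed = 2L)
  m <- grf_train(grf_build(cfg, colnames(task$features[[1]])),
                 task$features, targets)
  expect_true(m$early_stopped)
  expect_lt(m$epochs, 500L)
  expect_length(m$history, m$epochs)
  # running minimum of the loss history is non-increasing and finite
  expect_true(all(is.finite(m$history)))
  expect_true(all(diff(cummin(m$history)) <= 0))
})

test_that("training is deterministic given the seed", {
  task <- linear_task(n_trials = 4, T = 30)
  cfg <- model_config(lstm_units = 4L, mlp_sizes = c(4L), batch_size = 2L,
                      max_epochs = 5L, patience = 5L, seed = 9L)
  m1 <- grf_train(grf_build(cfg, colnames(task$features[[1]])),
                  task$features, task$targets)
  m2 <- grf_train(grf_build(cfg, colnames(task$features[[1]])),
                  task$features, task$targets)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$Wx_f, m2$weights$Wx_f)
})

test_that("feature mismatches are reported with names", {
  m <- grf_build(tiny_model_config(), feature_names = c("a", "b", "c"))
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "z")))
  expect_error(grf_predict(m, x), "missing.*c.*extra.*z")
})

test_that("models survive a save/load round trip", {
  task <- linear_task(n_trials = 2, T = 20)
  cfg <- model_config(lstm_units = 4L, mlp_sizes = c(4L), batch_size = 2L,
                      max_epochs = 2L, seed = 1L)
  m <- grf_train(grf_build(cfg, colnames(task$features[[1]])),
                 task$features, task$targets)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(grf_predict(m2, task$features[[1]])$samples,
               grf_predict(m, task$features[[1]])$samples, tolerance = 1e-12)
})
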