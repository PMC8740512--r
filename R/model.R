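#' Network and training configuration
#'
#' Defaults follow the published training recipe: a bidirectional LSTM
#' whose forward and time-reversed outputs are averaged elementwise,
#' followed by a per-frame MLP with three rectifier hidden layers of 128,
#' 384 and 320 neurons and a linear scalar output; 20% dropout on the
#' inputs and 40% on the LSTM output; Adam with learning rate 0.001, batch
#' size 32, mean-squared-error loss; at most 1,000 epochs with early
#' stopping once the training loss fails to improve by 0.001 for 30
#' consecutive epochs. The LSTM width is not pinned down by the recipe and
#' defaults to 128; it is deliberately configurable.
#'
#' @param lstm_units Hidden units per LSTM direction.
#' @param mlp_sizes Integer vector of MLP hidden-layer sizes.
#' @param input_dropout,post_lstm_dropout Dropout rates in `[0, 1)`.
#' @param batch_size Sequences per Adam update.
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch cap.
#' @param min_delta Minimum training-loss improvement counted as progress.
#' @param patience Epochs without improvement before stopping.
#' @param seed Seed fixing weight initialization, shuffling and dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(lstm_units = 128L, mlp_sizes = c(128L, 384L, 320L),
                         input_dropout = 0.20, post_lstm_dropout = 0.40,
                         batch_size = 32L, learning_rate = 0.001,
                         max_epochs = 1000L, min_delta = 0.001,
                         patience = 30L, seed = 1L) {
  stopifnot(lstm_units > 0, all(mlp_sizes > 0),
            input_dropout >= 0, input_dropout < 1,
            post_lstm_dropout >= 0, post_lstm_dropout < 1,
            batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1)
  structure(list(lstm_units = as.integer(lstm_units),
                 mlp_sizes = as.integer(mlp_sizes),
                 input_dropout = input_dropout,
                 post_lstm_dropout = post_lstm_dropout,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 min_delta = min_delta, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained GRF prediction network
#'
#' @param cfg A [model_config()].
#' @param feature_names Character vector of input feature names; its length
#'   sets the input width (13 with foot-strike features, 10 without).
#' @return A `grf_model` object (untrained).
#' @export
grf_build <- function(cfg = model_config(), feature_names = FEATURE_NAMES) {
  stopifnot(inherits(cfg, "model_config"), length(feature_names) >= 1)
  weights <- nn_init_weights(length(feature_names), cfg$lstm_units,
                             cfg$mlp_sizes, cfg$seed)
  structure(list(config = cfg, feature_names = feature_names,
                 weights = weights, history = numeric(0), epochs = 0L,
                 trained = FALSE, norm_params = NULL),
            class = "grf_model")
}

#' @export
print.grf_model <- function(x, ...) {
  cat(sprintf(
    "<grf_model> BiLSTM(%d, avg) + MLP(%s) | %d features | %s (%d epochs)\n",
    x$config$lstm_units, paste(x$config$mlp_sizes, collapse = "/"),
    length(x$feature_names),
    if (x$trained) "trained" else "untrained", x$epochs))
  invisible(x)
}

#' Train the network on feature sequences and GRF targets
#'
#' Minimizes per-frame MSE with Adam. All training sequences must share
#' one length (full trials are the training samples; shorter sequences are
#' acceptable for desk-scale runs provided they are equal). Early stopping
#' monitors the training loss.
#'
#' @param model A `grf_model` from [grf_build()].
#' @param features List of `T x F` scaled feature matrices.
#' @param targets List of length-`T` GRF vectors in BW.
#' @param norm_params Optional `norm_params` to attach to the model.
#' @return The trained `grf_model` with loss `history` and `epochs` filled.
#' @export
grf_train <- function(model, features, targets, norm_params = NULL) {
  stopifnot(inherits(model, "grf_model"))
  if (length(features) == 0L) stop("grf_train: empty training set")
  if (length(features) != length(targets))
    stop("grf_train: features and targets differ in length")
  for (f in features) check_feature_names(model, f)
  fit <- nn_train_cpp(model$weights,
                      lapply(features, unname_matrix),
                      lapply(targets, as.numeric),
                      model$config, model$config$seed)
  model$weights <- fit$weights
  model$history <- as.numeric(fit$history)
  model$epochs <- as.integer(fit$epochs)
  model$early_stopped <- isTRUE(fit$early_stopped)
  model$trained <- TRUE
  if (!is.null(norm_params)) model$norm_params <- norm_params
  model
}

#' Predict a GRF waveform from a feature sequence
#'
#' Frame-by-frame prediction: the output has exactly one GRF value (BW)
#' per input frame, for any sequence length. Dropout is inert at
#' inference, so repeated calls are bit-identical.
#'
#' @param model A trained `grf_model`.
#' @param seq A `T x F` scaled feature matrix (column names must match the
#'   model's features), or a list of them.
#' @param rate Output rate recorded on the returned trace (Hz).
#' @return A `signal_trace` of predicted normal GRF in BW (or a list).
#' @export
grf_predict <- function(model, seq, rate = 500) {
  stopifnot(inherits(model, "grf_model"))
  single <- is.matrix(seq)
  seqs <- if (single) list(seq) else seq
  for (f in seqs) check_feature_names(model, f)
  preds <- nn_predict_cpp(model$weights, lapply(seqs, unname_matrix))
  out <- lapply(preds, function(p)
    signal_trace(p, rate, axis = "grf_normal_BW", units = "BW"))
  if (single) out[[1]] else out
}

check_feature_names <- function(model, x) {
  nm <- colnames(x)
  if (is.null(nm)) {
    if (ncol(x) != length(model$feature_names))
      stop(sprintf("feature width %d does not match model width %d",
                   ncol(x), length(model$feature_names)))
    return(invisible(TRUE))
  }
  if (!identical(nm, model$feature_names)) {
    missing <- setdiff(model$feature_names, nm)
    extra <- setdiff(nm, model$feature_names)
    stop("feature mismatch; missing: [", paste(missing, collapse = ", "),
         "], extra: [", paste(extra, collapse = ", "), "]")
  }
  invisible(TRUE)
}

unname_matrix <- function(x) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  attr(x, "norm_params") <- NULL
  x
}

#' Save / load a trained model as plain text
#'
#' Weights go to an RDS-free JSON representation so models survive
#' text-only environments; config, feature names and normalization
#' parameters ride along.
#'
#' @param model A `grf_model`.
#' @param path Output file (JSON).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "grf_model"))
  obj <- list(config = unclass(model$config),
              feature_names = model$feature_names,
              weights = model$weights,
              history = model$history, epochs = model$epochs,
              trained = model$trained,
              norm_params = if (!is.null(model$norm_params))
                unclass(model$norm_params) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  w <- obj$weights
  w$Wx_f <- as_mat(w$Wx_f); w$Wh_f <- as_mat(w$Wh_f)
  w$Wx_b <- as_mat(w$Wx_b); w$Wh_b <- as_mat(w$Wh_b)
  w$b_f <- as.numeric(w$b_f); w$b_b <- as.numeric(w$b_b)
  w$mlp_W <- lapply(w$mlp_W, as_mat)
  w$mlp_b <- lapply(w$mlp_b, as.numeric)
  np <- NULL
  if (!is.null(obj$norm_params))
    np <- structure(list(min = unlist(obj$norm_params$min),
                         max = unlist(obj$norm_params$max),
                         features = obj$norm_params$features),
                    class = "norm_params")
  structure(list(config = cfg, feature_names = obj$feature_names,
                 weights = w, history = as.numeric(obj$history),
                 epochs = as.integer(obj$epochs),
                 trained = isTRUE(obj$trained), norm_params = np),
            class = "grf_model")
}
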