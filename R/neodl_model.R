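# The neoDL stratifier: a recurrent network that consumes each patient's
# ordered valid-feature vector as a length-T sequence of scalars
# (T = number of valid features), through two LSTM layers (128 and 32 units
# by default), a sigmoid fully connected layer (8 units) and a sigmoid
# output unit. Trained with MSE loss and Adam on 0/1 survival labels
# (1 = long-term). The numerical core lives in compiled code; this file
# handles configuration, weight initialization, the scaler contract and
# serialization.

#' Model and pipeline configuration
#'
#' Collects the tunable parameters of the stratifier and of the validation
#' protocol. Defaults follow the reference architecture: LSTM layers of 128
#' and 32 units, a fully connected layer of 8 units, MSE loss, Adam with
#' learning rate 1e-3, 1000 epochs, batch size 32, classification threshold
#' 0.5.
#'
#' @param hidden Integer vector `c(lstm1, lstm2, fc)` of layer sizes.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param threshold Probability cutoff for the predicted label.
#' @param seed Master seed for weight initialization and shuffling.
#' @param alpha Screening threshold on the Wald p-value.
#' @param max_features Cap on the number of valid features (smallest p
#'   first); `Inf` keeps all.
#' @param k Number of survival clusters.
#' @param split_ratio Training fraction of each stratum in validation
#'   splits.
#' @param n_trials Number of repeated split trials.
#' @param model_mode `"best_trial"` (model of the most significant trial) or
#'   `"full"` (retrain on the whole cohort after validation).
#' @return A list of class `neodl_config`.
#' @export
neodl_config <- function(hidden = c(128L, 32L, 8L), epochs = 1000L,
                         lr = 1e-3, batch_size = 32L, threshold = 0.5,
                         seed = 20210723L, alpha = 0.05,
                         max_features = Inf, k = 2L, split_ratio = 0.6,
                         n_trials = 300L,
                         model_mode = c("best_trial", "full")) {
  stopifnot(length(hidden) == 3L, all(hidden >= 1L), epochs >= 1L,
            lr > 0, batch_size >= 1L, threshold > 0, threshold < 1,
            split_ratio > 0, split_ratio < 1, n_trials >= 1L, k >= 1L)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 threshold = threshold, seed = as.integer(seed),
                 alpha = alpha, max_features = max_features,
                 k = as.integer(k), split_ratio = split_ratio,
                 n_trials = as.integer(n_trials),
                 model_mode = match.arg(model_mode)),
            class = "neodl_config")
}

# Glorot-uniform initial weights; forget-gate biases start at 1 (standard
# LSTM practice, speeds up early gradient flow through the cell state).
init_weights <- function(n_features, hidden, seed) {
  h1 <- hidden[1]; h2 <- hidden[2]; fc <- hidden[3]
  glorot <- function(r, c) {
    s <- sqrt(6 / (r + c))
    matrix(stats::runif(r * c, -s, s), r, c)
  }
  lstm_bias <- function(h) {
    b <- matrix(0, 4 * h, 1)
    b[(h + 1):(2 * h), 1] <- 1
    b
  }
  with_seed(seed, list(
    W1 = glorot(4 * h1, 1), U1 = glorot(4 * h1, h1), b1 = lstm_bias(h1),
    W2 = glorot(4 * h2, h1), U2 = glorot(4 * h2, h2), b2 = lstm_bias(h2),
    Wd = glorot(fc, h2), bd = matrix(0, fc, 1),
    Wo = glorot(1, fc), bo = matrix(0, 1, 1)))
}

#' Train the neoDL stratifier
#'
#' Trains the recurrent stratifier on a raw (unscaled) valid-feature matrix
#' and binary labels. The feature matrix is z-scored with `scaler` (fitted
#' on `x` itself when omitted); the scaler and the feature ordering travel
#' with the model, and prediction refuses inputs whose feature list or order
#' differs.
#'
#' @param x Patients x valid-features numeric matrix (raw scale).
#' @param labels 0/1 vector, 1 = long-term survival group.
#' @param config A [neodl_config()].
#' @param scaler Optional pre-fitted [zscaler_fit()] (the cohort-level
#'   scaler); default fits on `x`.
#' @param seed Seed for weight initialization and minibatch shuffling;
#'   defaults to `config$seed`.
#' @return Object of class `neodl_model` with elements `weights`, `scaler`,
#'   `features`, `config`, `history` (per-epoch loss and training accuracy).
#' @export
train_neodl <- function(x, labels, config = neodl_config(), scaler = NULL,
                        seed = config$seed) {
  x <- as.matrix(x)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(labels) != nrow(x)) stop("labels do not match rows of x")
  if (is.null(scaler)) scaler <- zscaler_fit(x)
  z <- impute_masked(zscaler_apply(scaler, x))
  w0 <- init_weights(ncol(x), config$hidden, seed)
  fit <- lstm_train_cpp(z, as.numeric(labels), w0,
                        epochs = config$epochs,
                        batch = min(config$batch_size, nrow(z)),
                        lr = config$lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, seed = seed)
  structure(list(
    weights = fit$weights, scaler = scaler, features = colnames(x),
    config = config,
    history = data.frame(epoch = seq_len(config$epochs),
                         loss = as.numeric(fit$loss),
                         accuracy = as.numeric(fit$accuracy))),
    class = "neodl_model")
}

#' @export
print.neodl_model <- function(x, ...) {
  h <- x$config$hidden
  cat("neoDL stratifier: LSTM(", h[1], ") -> LSTM(", h[2], ") -> FC(", h[3],
      ", sigmoid) -> sigmoid; ", length(x$features),
      " features; final training loss ",
      signif(utils::tail(x$history$loss, 1), 3), ", accuracy ",
      signif(utils::tail(x$history$accuracy, 1), 3), "\n", sep = "")
  invisible(x)
}

#' Predict with a trained stratifier
#'
#' Applies the stored z-scaler and the trained network to a raw
#' valid-feature matrix. Columns must match the training features exactly
#' (names and order).
#'
#' @param object A `neodl_model`.
#' @param newdata Patients x features matrix on the raw scale.
#' @param ... Unused.
#' @return Data frame with `probability` (in `[0, 1]`) and `label`
#'   (threshold at the configured cutoff; 1 = long-term).
#' @export
predict.neodl_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$features)) {
    stop("feature columns do not match the model's training features")
  }
  z <- impute_masked(zscaler_apply(object$scaler, newdata))
  prob <- as.numeric(lstm_predict_cpp(z, object$weights))
  data.frame(probability = prob,
             label = as.integer(prob > object$config$threshold))
}

#' Save / load a trained stratifier
#'
#' Serializes weights, scaler, feature ordering and configuration into one
#' versioned JSON file. Loading refuses files whose feature-vocabulary hash
#' does not match the stored feature list (guards against silently applying
#' a model to a different featurization).
#'
#' @param model A `neodl_model`.
#' @param path Output (input) file path.
#' @return `write_neodl_model` the path invisibly; `read_neodl_model` the
#'   model.
#' @export
write_neodl_model <- function(model, path) {
  payload <- list(
    format = "neodl-model", version = 1L,
    vocab_hash = vocab_hash(model$features),
    features = model$features,
    scaler = list(mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd)),
    config = {
      u <- unclass(model$config)
      if (!is.finite(u$max_features)) u$max_features <- NULL
      u
    },
    weights = lapply(model$weights, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neodl_model
#' @export
read_neodl_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "neodl-model")) stop("not a neodl model file")
  feats <- as.character(p$features)
  if (!identical(vocab_hash(feats), p$vocab_hash)) {
    stop("vocabulary hash mismatch: model file is inconsistent or was ",
         "built against a different featurization")
  }
  weights <- lapply(p$weights, function(w) {
    matrix(as.numeric(w$data), w$dim[1], w$dim[2])
  })
  scaler <- structure(list(mean = stats::setNames(p$scaler$mean, feats),
                           sd = stats::setNames(p$scaler$sd, feats),
                           features = feats), class = "zscaler")
  cfg <- p$config
  config <- neodl_config(hidden = cfg$hidden, epochs = cfg$epochs,
                         lr = cfg$lr, batch_size = cfg$batch_size,
                         threshold = cfg$threshold, seed = cfg$seed,
                         alpha = cfg$alpha,
                         max_features = if (is.null(cfg$max_features) ||
                                            !is.finite(cfg$max_features))
                           Inf else cfg$max_features,
                         k = cfg$k, split_ratio = cfg$split_ratio,
                         n_trials = cfg$n_trials,
                         model_mode = cfg$model_mode)
  structure(list(weights = weights, scaler = scaler, features = feats,
                 config = config, history = NULL), class = "neodl_model")
}
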