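#' LSTM specification
#'
#' Stacked LSTM (hyperbolic-tangent state activation, sigmoid gates) with a
#' linear read-out, trained as sequence-to-sequence regression: one
#' time-normalized gait cycle (100 frames x 9 channels) in, one cycle
#' (100 x 2 angles) out, with the internal state reset between cycles.
#' Optimized by Adam on MSE plus an L2 weight penalty.  The reference
#' configuration is 2 layers x 512 cells and 100 epochs; the desk-scale
#' default used in examples and tests is 2 x 64 cells and 30 epochs.
#'
#' @param layers number of stacked LSTM layers (default 2).
#' @param cells hidden cells per layer (default 64; reference 512).
#' @param epochs training epochs (default 30; reference 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param minibatch sequences per minibatch (default 10).
#' @param weight_penalty L2 coefficient on the weight matrices
#'   (default 0.0025).
#' @param clipnorm global gradient-norm clip; 0 disables (default 5).
#' @param seed integer seed for initialization and shuffling.
#' @return object of class `lstm_spec`.
#' @export
lstm_spec <- function(layers = 2L, cells = 64L, epochs = 30L,
                      learning_rate = 0.001, minibatch = 10L,
                      weight_penalty = 0.0025, clipnorm = 5, seed = 1L) {
  if (layers < 1L || cells < 1L || epochs < 1L) fail("invalid LSTM size/epochs")
  if (learning_rate <= 0) fail("learning rate must be positive")
  structure(list(layers = as.integer(layers), cells = as.integer(cells),
                 state_activation = "tanh", optimizer = "adam",
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 weight_penalty = weight_penalty, clipnorm = clipnorm,
                 seed = as.integer(seed)),
            class = "lstm_spec")
}

# internal: seeded initial weights.  Glorot-uniform input weights,
# orthogonal recurrent weights (per gate block) and unit forget-gate biases
# — the standard initialization of mainstream LSTM implementations, which
# markedly speeds convergence at small epoch budgets.
lstm_init_weights <- function(spec, d_in = 9L, d_out = 2L) {
  H <- spec$cells
  with_seed(spec$seed, {
    Wx <- Wh <- b <- vector("list", spec$layers)
    for (l in seq_len(spec$layers)) {
      d <- if (l == 1L) d_in else H
      r <- sqrt(6 / (d + 4 * H))
      Wx[[l]] <- matrix(runif(4 * H * d, -r, r), 4 * H, d)
      Wh[[l]] <- do.call(rbind, lapply(1:4, function(g)
        qr.Q(qr(matrix(rnorm(H * H), H, H)))))
      b[[l]] <- c(rep(0, H), rep(1, H), rep(0, 2 * H))
    }
    rv <- sqrt(6 / (H + d_out))
    V <- matrix(runif(d_out * H, -rv, rv), d_out, H)
    list(Wx = Wx, Wh = Wh, b = b, V = V, c = rep(0, d_out))
  })
}

# internal: list of (T x d) matrices -> T x d x N cube (passed as array)
cycles_to_cube <- function(cycles, field, d) {
  n <- length(cycles)
  T_ <- nrow(cycles[[1]][[field]])
  arr <- array(0, dim = c(T_, d, n))
  for (i in seq_len(n)) arr[, , i] <- cycles[[i]][[field]]
  arr
}

#' Train the LSTM estimator
#'
#' @param train_cycles list of cycles, each a list with `X` (100 x 9 scaled)
#'   and `Y` (100 x 2 scaled); subjects must be disjoint from validation.
#' @param val_cycles list in the same format used for the per-epoch
#'   validation MSE log (may be empty).
#' @param spec an [lstm_spec()].
#' @param scale_params per-column scaling parameters stored for inverse
#'   transforming predictions.
#' @param n_frames expected sequence length (default 100).
#' @return object of class `comcop_lstm` (also `comcop_model`).
#' @export
train_lstm <- function(train_cycles, val_cycles = list(), spec = lstm_spec(),
                       scale_params = NULL, n_frames = 100) {
  if (!length(train_cycles)) fail("empty training partition")
  for (cy in c(train_cycles, val_cycles))
    if (nrow(cy$X) != n_frames || ncol(cy$X) != 9L)
      fail("every sequence must be %d frames x 9 channels (got %d x %d)",
           n_frames, nrow(cy$X), ncol(cy$X))
  X <- cycles_to_cube(train_cycles, "X", 9L)
  Y <- cycles_to_cube(train_cycles, "Y", 2L)
  n <- length(train_cycles)
  w0 <- lstm_init_weights(spec)
  order <- with_seed(derive_seed(spec$seed, "shuffle"), {
    t(vapply(seq_len(spec$epochs), function(e) sample.int(n), integer(n)))
  })
  storage.mode(order) <- "integer"
  if (length(val_cycles)) {
    Xv <- cycles_to_cube(val_cycles, "X", 9L)
    Yv <- cycles_to_cube(val_cycles, "Y", 2L)
  } else {
    Xv <- array(0, dim = c(n_frames, 9, 0))
    Yv <- array(0, dim = c(n_frames, 2, 0))
  }
  fit <- lstm_train_cpp(X, Y, w0, order, spec$minibatch, spec$learning_rate,
                        spec$weight_penalty, Xv, Yv, spec$clipnorm)
  structure(list(kind = "lstm", weights = fit$weights, spec = spec,
                 training_log = data.frame(
                   epoch = seq_len(spec$epochs),
                   train_loss = as.numeric(fit$train_loss),
                   val_mse = as.numeric(fit$val_mse)),
                 scale_params = scale_params),
            class = c("comcop_lstm", "comcop_model"))
}

#' @export
print.comcop_lstm <- function(x, ...) {
  cat(sprintf("<comcop_lstm> %d x %d cells; %d epochs; final train loss %.4g\n",
              x$spec$layers, x$spec$cells, x$spec$epochs,
              x$training_log$train_loss[nrow(x$training_log)]))
  invisible(x)
}

#' Predict inclination angles from scaled IMU inputs
#'
#' Maps scaled inputs through the trained estimator and inverse-transforms
#' the outputs to degrees with the scaling parameters stored in the model.
#' The feed-forward model maps frame-by-frame (`newdata` is an n x 9
#' matrix); the LSTM maps whole cycles (`newdata` is one 100 x 9 matrix or a
#' list of them).
#'
#' @param object a trained `comcop_model`.
#' @param newdata scaled inputs (see Details).
#' @param type "degrees" (default, inverse-scaled) or "scaled".
#' @param ... unused.
#' @return n x 2 matrix (columns sagittal, frontal); for list input, the
#'   cycles stacked in order.
#' @export
predict.comcop_model <- function(object, newdata, type = c("degrees", "scaled"),
                                 ...) {
  type <- match.arg(type)
  if (object$kind == "ffann") {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != 9L) fail("expected 9 input channels, got %d", ncol(newdata))
    out <- ffann_predict_scaled(object$weights, newdata)
  } else {
    cyc <- if (is.matrix(newdata)) list(newdata) else newdata
    for (m in cyc) if (ncol(m) != 9L)
      fail("expected 9 input channels, got %d", ncol(m))
    X <- array(0, dim = c(nrow(cyc[[1]]), 9, length(cyc)))
    for (i in seq_along(cyc)) X[, , i] <- cyc[[i]]
    P <- lstm_predict_cpp(object$weights, X)
    out <- do.call(rbind, lapply(seq_len(dim(P)[3]), function(i) P[, , i]))
  }
  colnames(out) <- c("sagittal", "frontal")
  if (type == "scaled") return(out)
  sp <- object$scale_params
  if (is.null(sp)) fail("model carries no scale parameters; cannot return degrees")
  for (j in 1:2) out[, j] <- minmax_inverse(out[, j], sp$y_lo[j], sp$y_hi[j])
  out
}
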