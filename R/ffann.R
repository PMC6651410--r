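#' Feed-forward network specification
#'
#' One input layer (9 channels), one hidden layer with log-sigmoid units,
#' one linear output layer (2 planes).  Trained full-batch by iRprop-, a
#' gradient-sign optimizer in the same family of fast full-batch
#' backpropagation methods as scaled conjugate gradient, to a mean-square
#' error objective.  Training stops at `max_epochs` or when the validation
#' MSE has not improved for `patience` consecutive epochs, whichever comes
#' first; the best-validation weights are kept.
#'
#' @param hidden_units hidden-layer size (default 10).
#' @param max_epochs epoch cap (default 1000).
#' @param patience early-stopping patience in epochs (default 6).
#' @param seed integer seed for weight initialization.
#' @return object of class `ffann_spec`.
#' @export
ffann_spec <- function(hidden_units = 10L, max_epochs = 1000L,
                       patience = 6L, seed = 1L) {
  if (hidden_units < 1L) fail("hidden_units must be >= 1")
  if (patience < 1L || max_epochs < patience)
    fail("need max_epochs >= patience >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 hidden_activation = "logsig", output_activation = "linear",
                 optimizer = "irprop_minus",
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ffann_spec")
}

logsig <- function(z) 1 / (1 + exp(-z))

# internal: MSE loss and gradient of the 2-layer net, full batch
ffann_loss_grad <- function(w, X, Y) {
  H <- logsig(sweep(X %*% w$W1, 2, w$b1, `+`))
  Yhat <- sweep(H %*% w$W2, 2, w$b2, `+`)
  E <- Yhat - Y
  n <- length(E)
  dY <- 2 * E / n
  dW2 <- crossprod(H, dY)
  db2 <- colSums(dY)
  dH <- dY %*% t(w$W2) * H * (1 - H)
  list(loss = mean(E^2),
       grad = list(W1 = crossprod(X, dH), b1 = colSums(dH),
                   W2 = dW2, b2 = db2))
}

ffann_predict_scaled <- function(w, X) {
  H <- logsig(sweep(X %*% w$W1, 2, w$b1, `+`))
  sweep(H %*% w$W2, 2, w$b2, `+`)
}

#' Train the feed-forward estimator
#'
#' Frame-wise regression from the 9 scaled IMU channels to the 2 scaled
#' inclination angles.  Deterministic for a fixed spec seed and data.
#'
#' @param X_train,Y_train scaled training matrices (n x 9, n x 2).
#' @param X_val,Y_val scaled validation matrices (disjoint subjects).
#' @param spec an [ffann_spec()].
#' @param scale_params per-column scaling parameters (from
#'   [assemble_matrices()]); stored for inverse transforming predictions.
#' @return object of class `comcop_ffann` (also `comcop_model`).
#' @export
train_ffann <- function(X_train, Y_train, X_val, Y_val, spec = ffann_spec(),
                        scale_params = NULL) {
  if (!nrow(X_train) || !nrow(X_val)) fail("empty train or validation partition")
  stopifnot(ncol(X_train) == 9L, ncol(Y_train) == 2L)
  d <- ncol(X_train); h <- spec$hidden_units; k <- ncol(Y_train)
  w <- with_seed(spec$seed, list(
    W1 = matrix(rnorm(d * h, 0, 0.5), d, h), b1 = rnorm(h, 0, 0.1),
    W2 = matrix(rnorm(h * k, 0, 0.5), h, k), b2 = rnorm(k, 0, 0.1)))
  # iRprop-: per-weight step sizes adapted by gradient sign agreement
  step <- lapply(w, function(p) p * 0 + 0.01)
  gprev <- lapply(w, function(p) p * 0)
  eta_up <- 1.2; eta_dn <- 0.5; smax <- 1; smin <- 1e-9
  best <- list(val = Inf, w = w, epoch = 0L)
  wait <- 0L
  log_tr <- log_va <- numeric(0)
  for (ep in seq_len(spec$max_epochs)) {
    lg <- ffann_loss_grad(w, X_train, Y_train)
    for (nm in names(w)) {
      g <- lg$grad[[nm]]
      sgn <- sign(g * gprev[[nm]])
      step[[nm]] <- clip(step[[nm]] * ifelse(sgn > 0, eta_up,
                                             ifelse(sgn < 0, eta_dn, 1)),
                         smin, smax)
      g[sgn < 0] <- 0 # iRprop-: forget gradient after a sign change
      w[[nm]] <- w[[nm]] - sign(g) * step[[nm]]
      gprev[[nm]] <- g
    }
    val <- mean((ffann_predict_scaled(w, X_val) - Y_val)^2)
    log_tr <- c(log_tr, lg$loss); log_va <- c(log_va, val)
    if (val < best$val - 1e-12) {
      best <- list(val = val, w = w, epoch = ep); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(kind = "ffann", weights = best$w, spec = spec,
                 training_log = data.frame(epoch = seq_along(log_tr),
                                           train_mse = log_tr,
                                           val_mse = log_va),
                 best_epoch = best$epoch, scale_params = scale_params),
            class = c("comcop_ffann", "comcop_model"))
}

#' @export
print.comcop_ffann <- function(x, ...) {
  cat(sprintf("<comcop_ffann> %d hidden units; trained %d epochs (best at %d, val MSE %.4g)\n",
              x$spec$hidden_units, nrow(x$training_log), x$best_epoch,
              min(x$training_log$val_mse)))
  invisible(x)
}
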