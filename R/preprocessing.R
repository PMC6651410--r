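#' Low-pass Butterworth filter specification
#'
#' @param cutoff cutoff frequency (Hz), 0 < cutoff < rate/2 at use time.
#' @param order filter order; even and positive (default 4).
#' @param zero_phase apply forward-backward for zero phase lag (default
#'   TRUE).  A single causal pass is available for completeness; note the
#'   double pass squares the magnitude response (amplitude 1/2 at cutoff).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff, order = 4L, zero_phase = TRUE) {
  if (cutoff <= 0) fail("cutoff must be positive")
  if (order <= 0 || order %% 2 != 0) fail("order must be even and positive")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 kind = "lowpass_butterworth", zero_phase = zero_phase),
            class = "filter_spec")
}

#' Apply a low-pass Butterworth filter
#'
#' Fourth-order (by default) Butterworth low-pass with unit DC gain.  The
#' default zero-phase mode filters forward then backward with odd-reflection
#' padding of 3 x order samples at each end to suppress edge transients.
#'
#' @param x numeric series; length must exceed 3 x order.
#' @param rate sampling rate (Hz); must exceed 2 x cutoff.
#' @param spec a [filter_spec()].
#' @return filtered series, same length as x.
#' @export
butterworth_lowpass <- function(x, rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= rate / 2)
    fail("cutoff %.3g Hz is at or above Nyquist (%.3g Hz)",
         spec$cutoff, rate / 2)
  n <- length(x)
  if (n <= 3 * spec$order)
    fail("series too short (%d) for order-%d filtering", n, spec$order)
  bf <- signal::butter(spec$order, spec$cutoff / (rate / 2), type = "low")
  pad <- min(3L * spec$order, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  # seed the filter history with the first sample so a constant input is in
  # steady state from sample one (the filter has unit DC gain); combined with
  # the odd-reflection padding this suppresses edge transients
  run <- function(z) as.numeric(signal::filter(
    bf$b, bf$a, z,
    init.x = rep(z[1], spec$order), init.y = rep(z[1], spec$order)))
  y <- run(xp)
  if (spec$zero_phase) y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Scale a column linearly to [-1, 1]
#'
#' x' = 2 (x - lo) / (hi - lo) - 1; exact round trip with
#' [minmax_inverse()].
#'
#' @param x numeric values.
#' @param lo,hi scaling bounds, hi > lo (typically the column min and max).
#' @return scaled values.
#' @export
minmax_scale <- function(x, lo, hi) {
  if (!(hi > lo)) fail("degenerate column: hi (%g) must exceed lo (%g)", hi, lo)
  2 * (x - lo) / (hi - lo) - 1
}

#' @rdname minmax_scale
#' @param xs scaled values to invert.
#' @export
minmax_inverse <- function(xs, lo, hi) (xs + 1) / 2 * (hi - lo) + lo

#' Resample IMU channels onto a gait-cycle window
#'
#' Cuts each of the 9 channels to the cycle window and time-normalizes it to
#' `n` frames with the same interpolator as [time_normalize()], so model
#' inputs and outputs are frame-aligned.
#'
#' @param imu data.frame with a `time` column and the 9 channels ax..mz.
#' @param window c(start, end) in seconds; must lie within the stream.
#' @param n frames (default 100).
#' @return n x 9 matrix.
#' @export
resample_to_cycle <- function(imu, window, n = 100) {
  chans <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  if (!all(c("time", chans) %in% names(imu)))
    fail("imu must contain columns time and %s", paste(chans, collapse = ","))
  t <- imu$time
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9)
    fail("cycle window [%.3f, %.3f] exceeds stream coverage [%.3f, %.3f]",
         window[1], window[2], t[1], t[length(t)])
  xout <- seq(window[1], window[2], length.out = n)
  out <- vapply(chans, function(ch)
    spline(t, imu[[ch]], xout = xout, method = "fmm")$y, numeric(n))
  colnames(out) <- chans
  out
}

#' Assemble learning matrices from per-cycle blocks
#'
#' Stacks time-normalized cycles into the input matrix X (frames x 9,
#' channel order accel, gyro, mag) and the output matrix Y (frames x 2,
#' sagittal then frontal), scales every column linearly to [-1, 1], and
#' records per-row provenance and the per-column scaling parameters.
#' Scaling mode `"paper"` takes each column's min/max over the whole matrix;
#' `"train_only"` takes them over the rows of `train_subjects` only
#' (leakage-safe alternative).
#'
#' @param cycles list; each element a list with fields `subject`, `trial`,
#'   `speed`, `X` (100 x 9) and `Y` (100 x 2 degrees, sagittal/frontal).
#' @param scaling "paper" or "train_only".
#' @param train_subjects subject ids defining the scaling rows when
#'   `scaling = "train_only"`.
#' @param n_frames expected frames per cycle (default 100).
#' @return object of class `dataset_matrices` with elements X, Y (scaled),
#'   row_meta, scale_params, scaling.
#' @export
assemble_matrices <- function(cycles, scaling = c("paper", "train_only"),
                              train_subjects = NULL, n_frames = 100) {
  scaling <- match.arg(scaling)
  for (cy in cycles) {
    if (nrow(cy$X) != n_frames || nrow(cy$Y) != n_frames ||
        ncol(cy$X) != 9L || ncol(cy$Y) != 2L)
      fail("ragged cycle for subject %s trial %s speed %s: X %dx%d, Y %dx%d",
           cy$subject, cy$trial, cy$speed, nrow(cy$X), ncol(cy$X),
           nrow(cy$Y), ncol(cy$Y))
  }
  X <- do.call(rbind, lapply(cycles, `[[`, "X"))
  Y <- do.call(rbind, lapply(cycles, `[[`, "Y"))
  colnames(X) <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  colnames(Y) <- c("sagittal", "frontal")
  row_meta <- do.call(rbind, lapply(cycles, function(cy)
    data.frame(subject = cy$subject, trial = cy$trial, speed = cy$speed,
               frame = seq_len(n_frames))))
  rows <- if (scaling == "paper") rep(TRUE, nrow(X)) else {
    if (is.null(train_subjects))
      fail("train_only scaling needs train_subjects")
    row_meta$subject %in% train_subjects
  }
  sp <- list(x_lo = apply(X[rows, , drop = FALSE], 2, min),
             x_hi = apply(X[rows, , drop = FALSE], 2, max),
             y_lo = apply(Y[rows, , drop = FALSE], 2, min),
             y_hi = apply(Y[rows, , drop = FALSE], 2, max))
  for (j in 1:9) X[, j] <- minmax_scale(X[, j], sp$x_lo[j], sp$x_hi[j])
  for (j in 1:2) Y[, j] <- minmax_scale(Y[, j], sp$y_lo[j], sp$y_hi[j])
  structure(list(X = X, Y = Y, row_meta = row_meta, scale_params = sp,
                 scaling = scaling, n_frames = n_frames),
            class = "dataset_matrices")
}

#' @export
print.dataset_matrices <- function(x, ...) {
  cat(sprintf("<dataset_matrices> X %d x %d, Y %d x %d; %d subjects; scaling '%s'\n",
              nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y),
              length(unique(x$row_meta$subject)), x$scaling))
  invisible(x)
}

# internal: extract per-cycle sequences (scaled) for the given subjects
cycle_blocks <- function(mat, subjects) {
  stopifnot(inherits(mat, "dataset_matrices"))
  rm <- mat$row_meta
  key <- interaction(rm$subject, rm$trial, rm$speed, drop = TRUE)
  keep <- rm$subject %in% subjects
  ids <- unique(key[keep])
  lapply(ids, function(id) {
    rows <- which(key == id)
    list(X = mat$X[rows, , drop = FALSE], Y = mat$Y[rows, , drop = FALSE],
         subject = rm$subject[rows[1]], trial = rm$trial[rows[1]],
         speed = rm$speed[rows[1]])
  })
}

# internal: row indices for the given subjects
subject_rows <- function(mat, subjects) which(mat$row_meta$subject %in% subjects)
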