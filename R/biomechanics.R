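#' Whole-body COM by the kinematic method
#'
#' The mass-weighted sum of the 15 per-segment COM trajectories:
#' COM(t) = sum_i f_i * seg_i(t).
#'
#' @param segment_coms n x 3 x 15 array (or list of 15 n x 3 matrices) of
#'   segment COM trajectories (m).
#' @param model an [anthropometric_model()].
#' @return n x 3 matrix of whole-body COM positions (m).
#' @export
whole_body_com <- function(segment_coms, model = anthropometric_model()) {
  if (is.list(segment_coms)) {
    nr <- vapply(segment_coms, nrow, 1L)
    if (length(segment_coms) != 15L)
      fail("need 15 segment trajectories, got %d", length(segment_coms))
    if (length(unique(nr)) != 1L) fail("segment trajectories have unequal lengths")
    segment_coms <- array(unlist(segment_coms),
                          dim = c(nr[1], 3, 15))
  }
  d <- dim(segment_coms)
  if (length(d) != 3L || d[3] != 15L)
    fail("segment_coms must be an n x 3 x 15 array")
  f <- model$mass_fractions
  out <- matrix(0, d[1], 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in 1:15) out <- out + f[i] * segment_coms[, , i]
  out
}

#' Net centre of pressure from two force plates
#'
#' The net COP is the per-frame weighted mean of the two per-plate COPs,
#' weighted by each plate's share of the vertical ground reaction force:
#' COP_net = (fz1 * cop1 + fz2 * cop2) / (fz1 + fz2).
#'
#' Frames where both forces are zero have no defined COP; they are returned
#' as NA and flagged with a warning so downstream cycle extraction can
#' exclude them.
#'
#' @param cop_1,cop_2 n x 2 matrices of per-plate COP positions (m).
#' @param fz_1,fz_2 nonnegative vertical force series (N).
#' @return n x 2 matrix of net COP positions; attribute `invalid` marks
#'   frames with zero total force.
#' @export
net_cop <- function(cop_1, cop_2, fz_1, fz_2) {
  cop_1 <- as.matrix(cop_1); cop_2 <- as.matrix(cop_2)
  n <- length(fz_1)
  if (length(fz_2) != n || nrow(cop_1) != n || nrow(cop_2) != n)
    fail("net_cop inputs must have equal lengths")
  if (any(fz_1 < -1e-9) || any(fz_2 < -1e-9))
    fail("vertical forces must be nonnegative")
  tot <- fz_1 + fz_2
  invalid <- tot <= 0
  if (any(invalid))
    warning(sprintf("net_cop: %d frame(s) with zero total vertical force excluded",
                    sum(invalid)))
  w1 <- ifelse(invalid, NA_real_, fz_1 / ifelse(invalid, 1, tot))
  out <- cbind(x = w1 * cop_1[, 1] + (1 - w1) * cop_2[, 1],
               y = w1 * cop_1[, 2] + (1 - w1) * cop_2[, 2])
  attr(out, "invalid") <- invalid
  out
}

#' COM-COP inclination angles
#'
#' The inclination angle is the instantaneous orientation of the line from
#' the COP to the COM relative to the vertical through the COP.  With
#' P = COM - COP (COP lifted to the ground plane) and Z the global vertical
#' unit vector, v = (P x Z) / ||P|| and the plane angles are arcsines of the
#' components of v: sagittal IA = asin(P_x / ||P||) (anterior lean positive)
#' and frontal IA = asin(P_y / ||P||) (lean toward the subject's left
#' positive), reported in degrees.
#'
#' @param com n x 3 COM trajectory (m); height measured from the ground
#'   plane and strictly positive.
#' @param cop_net n x 2 net COP trajectory on the ground plane (m).
#' @param provenance optional list (subject/trial/speed) carried along.
#' @return an `ia_series` data.frame with columns sagittal and frontal (deg).
#' @export
inclination_angles <- function(com, cop_net, provenance = NULL) {
  com <- as.matrix(com); cop_net <- as.matrix(cop_net)
  if (nrow(com) != nrow(cop_net)) fail("com and cop_net lengths differ")
  if (any(com[, 3] <= 0)) fail("COM height above ground must be positive")
  P <- cbind(com[, 1] - cop_net[, 1], com[, 2] - cop_net[, 2], com[, 3])
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm == 0)) fail("COM coincides with COP: inclination undefined")
  # v = (P x Z) / ||P|| with Z = (0, 0, 1): v = (P_y, -P_x, 0) / ||P||
  v <- cbind(P[, 2], -P[, 1], 0) / nrm
  stopifnot(all(abs(v) <= 1 + 1e-12))
  ia_series(sagittal = asin(clip(-v[, 2], -1, 1)) * 180 / pi,
            frontal  = asin(clip(v[, 1], -1, 1)) * 180 / pi,
            provenance = provenance)
}

#' Inclination angle series container
#'
#' @param sagittal,frontal angles per frame (degrees), |angle| < 90.
#' @param provenance optional list of subject/trial/speed identifiers.
#' @return data.frame of class `ia_series`.
#' @export
ia_series <- function(sagittal, frontal, provenance = NULL) {
  if (length(sagittal) != length(frontal))
    fail("sagittal and frontal series must have equal length")
  if (any(abs(sagittal) >= 90) || any(abs(frontal) >= 90))
    fail("inclination angles must lie strictly inside (-90, 90) degrees")
  structure(data.frame(sagittal = sagittal, frontal = frontal),
            provenance = provenance,
            class = c("ia_series", "data.frame"))
}

#' @export
print.ia_series <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<ia_series> %d frames; sagittal [%.2f, %.2f] deg; frontal [%.2f, %.2f] deg%s\n",
              nrow(x), min(x$sagittal), max(x$sagittal),
              min(x$frontal), max(x$frontal),
              if (!is.null(pv)) paste0("; ", paste(unlist(pv), collapse = "/"))
              else ""))
  invisible(x)
}

#' Segment gait cycles from events
#'
#' Two policies.  `paper_modified` (default): a cycle runs from the toe-off
#' of one foot to the next heel strike of that same foot — i.e. the single
#' support period of the contralateral foot, the window analysed during a
#' two-plate crossing.  `standard`: heel strike to the next ipsilateral heel
#' strike.
#'
#' @param events a `gait_events` data.frame (columns time, foot, type).
#' @param policy "paper_modified" or "standard".
#' @return data.frame with columns start, end (s) and stance_foot (the foot
#'   in single support for `paper_modified`; the leading foot for
#'   `standard`), one row per cycle, ordered by start time.
#' @export
segment_gait_cycle <- function(events, policy = c("paper_modified", "standard")) {
  policy <- match.arg(policy)
  ev <- as.data.frame(events)
  if (!all(c("time", "foot", "type") %in% names(ev)))
    fail("events must have columns time, foot, type")
  ev <- ev[order(ev$time), ]
  out <- NULL
  if (policy == "paper_modified") {
    for (ft in c("R", "L")) {
      to <- ev$time[ev$foot == ft & ev$type == "toe_off"]
      hs <- ev$time[ev$foot == ft & ev$type == "heel_strike"]
      for (t0 in to) {
        t1 <- hs[hs > t0 + 1e-9]
        if (length(t1))
          out <- rbind(out, data.frame(start = t0, end = t1[1],
                                       stance_foot = setdiff(c("R", "L"), ft)))
      }
    }
  } else {
    for (ft in c("R", "L")) {
      hs <- sort(ev$time[ev$foot == ft & ev$type == "heel_strike"])
      if (length(hs) >= 2L)
        out <- rbind(out, data.frame(start = hs[-length(hs)], end = hs[-1],
                                     stance_foot = ft))
    }
  }
  if (is.null(out) || !nrow(out))
    fail("insufficient events for one cycle (%d events given)", nrow(ev))
  out <- out[order(out$start), ]
  if (any(out$end <= out$start)) fail("degenerate cycle window")
  rownames(out) <- NULL
  out
}

#' Time-normalize a series to a fixed number of frames
#'
#' Resamples a per-frame series onto n equally spaced points spanning its
#' time range (100% gait-cycle normalization), preserving the endpoints
#' exactly.  Cubic spline interpolation by default (smooth kinematic data);
#' linear available.
#'
#' @param y numeric series (length >= 2).
#' @param n output length, default 100.
#' @param t optional time vector matching y; defaults to a uniform grid.
#' @param method "cubic" (spline) or "linear".
#' @return numeric vector of length n.
#' @export
time_normalize <- function(y, n = 100, t = NULL, method = c("cubic", "linear")) {
  method <- match.arg(method)
  if (length(y) < 2L) fail("series must have at least 2 samples")
  if (n < 2L) fail("n must be at least 2")
  if (is.null(t)) t <- seq_along(y)
  if (length(t) != length(y)) fail("t and y lengths differ")
  xout <- seq(t[1], t[length(t)], length.out = n)
  if (method == "cubic") spline(t, y, xout = xout, method = "fmm")$y
  else approx(t, y, xout = xout)$y
}

#' Ground-truth inclination angles for one trial
#'
#' The full measurement pipeline on a recorded trial: low-pass filter the
#' mocap and force streams (4th-order zero-phase Butterworth, 7 Hz), compute
#' the whole-body COM from the 15 segments, the net COP from the two plates,
#' interpolate the net COP onto the mocap clock, form the inclination
#' angles, cut the selected gait cycle and time-normalize it to `n_frames`.
#'
#' @param trial a `trial_recording`.
#' @param model an [anthropometric_model()].
#' @param mocap_cutoff low-pass cutoff for mocap/force streams (Hz).
#' @param policy cycle policy, see [segment_gait_cycle()].
#' @param cycle which cycle to analyse: "middle" (default, the cycle nearest
#'   the trial midpoint — the two-plate crossing) or a row index into the
#'   cycle table.
#' @param n_frames frames after normalization (default 100).
#' @return list with `ia` (an `ia_series` of n_frames rows) and `window`
#'   (c(start, end) in seconds).
#' @export
trial_inclination_angles <- function(trial, model = anthropometric_model(),
                                     mocap_cutoff = 7,
                                     policy = "paper_modified",
                                     cycle = "middle", n_frames = 100) {
  stopifnot(inherits(trial, "trial_recording"))
  fs <- filter_spec(cutoff = mocap_cutoff)
  segs <- trial$segment_coms
  for (i in seq_len(dim(segs)[3])) for (j in 1:3)
    segs[, j, i] <- butterworth_lowpass(segs[, j, i], trial$mocap_rate, fs)
  com <- whole_body_com(segs, model)

  g <- trial$grf
  fz1 <- pmax(butterworth_lowpass(g$fz1, trial$force_rate, fs), 0)
  fz2 <- pmax(butterworth_lowpass(g$fz2, trial$force_rate, fs), 0)
  cop1 <- apply(g$cop1, 2, butterworth_lowpass, rate = trial$force_rate,
                spec = fs)
  cop2 <- apply(g$cop2, 2, butterworth_lowpass, rate = trial$force_rate,
                spec = fs)
  cnet <- net_cop(cop1, cop2, fz1, fz2)
  ok <- !attr(cnet, "invalid")
  cop_m <- cbind(approx(g$t[ok], cnet[ok, 1], xout = trial$t_mocap, rule = 2)$y,
                 approx(g$t[ok], cnet[ok, 2], xout = trial$t_mocap, rule = 2)$y)

  ia <- inclination_angles(com, cop_m,
                           provenance = list(subject = trial$subject_id,
                                             trial = trial$meta$trial_id,
                                             speed = trial$speed_class))
  cyc <- segment_gait_cycle(trial$events, policy)
  win <- select_cycle(cyc, if (identical(cycle, "middle"))
    max(trial$t_mocap) / 2 else NULL, index = cycle)
  inwin <- trial$t_mocap >= win[1] - 1e-9 & trial$t_mocap <= win[2] + 1e-9
  tt <- trial$t_mocap[inwin]
  out <- ia_series(
    sagittal = time_normalize(ia$sagittal[inwin], n_frames, t = tt),
    frontal  = time_normalize(ia$frontal[inwin], n_frames, t = tt),
    provenance = attr(ia, "provenance"))
  list(ia = out, window = win)
}

# internal: pick one cycle window (nearest a target time, or by index)
select_cycle <- function(cycles, target_time = NULL, index = NULL) {
  if (!is.null(target_time)) {
    mid <- (cycles$start + cycles$end) / 2
    i <- which.min(abs(mid - target_time))
  } else {
    i <- as.integer(index)
    if (is.na(i) || i < 1L || i > nrow(cycles)) fail("invalid cycle index")
  }
  c(cycles$start[i], cycles$end[i])
}
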