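#' Sample a synthetic subject
#'
#' Draws anthropometrics from the population the study emulates (young adult
#' males, height 171.2 +/- 4.3 cm, mass 67.3 +/- 7.1 kg), truncated at
#' +/- 3 SD.  Derived quantities follow standard allometric fractions:
#' leg length = 0.53 x height, standing COM height = 0.55 x height, normal
#' step length = 0.78 x leg length.  The three self-selected walking speed
#' classes are encoded as dimensionless speed multipliers applied through
#' their square root to both cadence and step length.
#'
#' @param seed nonnegative integer; the same seed returns an identical
#'   subject.
#' @return an object of class `subject_params`.
#' @examples
#' s <- sample_subject(7)
#' s$height_cm
#' @export
sample_subject <- function(seed) {
  seed <- as.integer(seed)
  with_seed(seed, {
    height <- clip(rnorm(1, 171.2, 4.3), 171.2 - 3 * 4.3, 171.2 + 3 * 4.3)
    mass   <- clip(rnorm(1, 67.3, 7.1),  67.3 - 3 * 7.1,  67.3 + 3 * 7.1)
    cad    <- clip(rnorm(1, 112, 4), 100, 124)
    step_width <- clip(rnorm(1, 0.20, 0.012), 0.16, 0.24)
    sway_amp   <- clip(rnorm(1, 0.035, 0.004), 0.022, 0.047)
    vert_amp   <- clip(rnorm(1, 0.022, 0.003), 0.013, 0.031)
    tilt_amp   <- clip(rnorm(1, 3.0, 0.5), 1.5, 4.5)   # deg, step frequency
    obli_amp   <- clip(rnorm(1, 4.0, 0.6), 2.0, 6.0)   # deg, stride frequency
    rota_amp   <- clip(rnorm(1, 7.0, 1.0), 4.0, 10.0)  # deg, stride frequency
  })
  leg <- 0.53 * height / 100
  subject_params(
    subject_id = sprintf("S%04d", seed %% 10000L),
    height = height, mass = mass,
    leg_length = leg,
    preferred_cadence = cad,
    speed_scalars = c(slow = 0.85, normal = 1.0, fast = 1.15),
    com_height = 0.55 * height / 100,
    step_length = 0.78 * leg,
    step_width = step_width,
    sway_amp = sway_amp, vert_amp = vert_amp,
    trunk_amp_deg = c(tilt = tilt_amp, obliquity = obli_amp,
                      rotation = rota_amp),
    seed = seed)
}

#' Subject parameter container
#'
#' @param subject_id identifier string.
#' @param height standing height (cm), > 0.
#' @param mass body mass (kg), > 0.
#' @param leg_length leg length (m); must be < height/100.
#' @param preferred_cadence steps per minute at normal speed.
#' @param speed_scalars named multipliers for exactly the classes
#'   slow/normal/fast with slow < 1 < fast.
#' @param com_height,step_length,step_width,sway_amp,vert_amp,trunk_amp_deg,seed
#'   gait-model parameters (m, m, m, m, m, deg, int).
#' @return validated `subject_params` object.
#' @export
subject_params <- function(subject_id, height, mass, leg_length,
                           preferred_cadence,
                           speed_scalars = c(slow = 0.85, normal = 1.0,
                                             fast = 1.15),
                           com_height = 0.55 * height / 100,
                           step_length = 0.78 * leg_length,
                           step_width = 0.20, sway_amp = 0.035,
                           vert_amp = 0.022,
                           trunk_amp_deg = c(tilt = 3, obliquity = 4,
                                             rotation = 7),
                           seed = NA_integer_) {
  if (height <= 0 || mass <= 0) fail("height and mass must be positive")
  if (leg_length >= height / 100)
    fail("leg length (%.2f m) must be below height (%.2f m)",
         leg_length, height / 100)
  if (!setequal(names(speed_scalars), c("slow", "normal", "fast")))
    fail("speed_scalars must name exactly slow, normal, fast")
  if (!(speed_scalars[["slow"]] < 1 && speed_scalars[["fast"]] > 1))
    fail("need slow multiplier < 1 < fast multiplier")
  structure(list(subject_id = subject_id, height_cm = height, mass_kg = mass,
                 leg_length_m = leg_length,
                 preferred_cadence = preferred_cadence,
                 speed_scalars = speed_scalars, com_height_m = com_height,
                 step_length_m = step_length, step_width_m = step_width,
                 sway_amp_m = sway_amp, vert_amp_m = vert_amp,
                 trunk_amp_deg = trunk_amp_deg, seed = seed),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> %s: %.1f cm, %.1f kg, cadence %.0f spm\n",
              x$subject_id, x$height_cm, x$mass_kg, x$preferred_cadence))
  invisible(x)
}

#' IMU noise specification
#'
#' Additive white Gaussian noise per channel plus a small random-walk drift,
#' emulating the thermal-mechanical and electronic noise of a low-cost MEMS
#' sensor.  Defaults (accel 0.15 m/s^2, gyro 1.0 deg/s, mag 1.0 uT) keep the
#' raw traces visibly noisy but learnable.
#'
#' @param accel_sigma accelerometer white-noise SD (m/s^2), >= 0.
#' @param gyro_sigma gyroscope white-noise SD (deg/s), >= 0.
#' @param mag_sigma magnetometer white-noise SD (uT), >= 0.
#' @param drift_rate random-walk step SD as a fraction of the channel sigma.
#' @param seed integer; fully determines the noise realization.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(accel_sigma = 0.15, gyro_sigma = 1.0, mag_sigma = 1.0,
                       drift_rate = 0.02, seed = 0L) {
  if (any(c(accel_sigma, gyro_sigma, mag_sigma, drift_rate) < 0))
    fail("noise magnitudes must be nonnegative")
  structure(list(accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
                 mag_sigma = mag_sigma, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# ---------------------------------------------------------------------------
# Closed-form gait model
#
# COM: forward progression at the class speed + small fore-aft oscillation at
# step frequency; vertical oscillation at step frequency (2 per stride),
# highest at mid single support; mediolateral sway at stride frequency toward
# the stance foot.  Feet: alternating placements one step length apart; the
# leading foot lands 0.45 step lengths ahead of the COM.  Per-foot COP
# advances linearly heel (-0.04 m) to toe (+0.20 m) during stance.  Load
# transfer between feet uses complementary cosine ramps over the double
# support (10% of the stride), so the per-plate vertical forces always sum to
# m * (g + z..), the force consistent with the COM's vertical acceleration.
# ---------------------------------------------------------------------------

# internal: the full deterministic description of one trial's motion
gait_plan <- function(subject, speed_class, seed, duration) {
  mult <- subject$speed_scalars[[speed_class]]
  with_seed(seed, {
    jit_c <- runif(1, 0.98, 1.02)
    jit_l <- runif(1, 0.98, 1.02)
    phase <- runif(1)
    tilt_phase <- runif(1, -0.5, 0.5)
  })
  cad <- subject$preferred_cadence * sqrt(mult) * jit_c     # steps/min
  sl  <- subject$step_length_m * sqrt(mult) * jit_l         # m per step
  t_step <- 60 / cad
  t_stride <- 2 * t_step
  f <- 1 / t_stride
  t_hs0 <- 0.45 + phase * t_step
  list(speed_class = speed_class, mult = mult,
       cadence = cad, step_length = sl, t_step = t_step,
       t_stride = t_stride, f_stride = f, v = sl / t_step,
       t_hs0 = t_hs0, stance = 0.6 * t_stride, ds = 0.1 * t_stride,
       land_offset = 0.45 * sl, cop_heel = -0.04, cop_toe = 0.20,
       tilt_phase = tilt_phase, tilt0 = 5 * pi / 180,
       duration = duration, subject = subject)
}

# internal: COM position at times t (n x 3, global frame)
plan_com <- function(p, t) {
  s <- p$subject
  tau <- t - p$t_hs0
  x <- p$v * tau + 0.01 * sin(4 * pi * p$f_stride * tau)
  y <- -s$sway_amp_m * sin(2 * pi * p$f_stride * (tau - 0.05 * p$t_stride))
  z <- s$com_height_m -
    s$vert_amp_m * cos(4 * pi * p$f_stride * (tau - 0.05 * p$t_stride))
  cbind(x = x, y = y, z = z)
}

# internal: COM vertical acceleration at times t
plan_com_zacc <- function(p, t) {
  s <- p$subject
  w <- 4 * pi * p$f_stride
  s$vert_amp_m * w^2 *
    cos(w * (t - p$t_hs0 - 0.05 * p$t_stride))
}

# internal: heel-strike times for one foot covering [0, duration] + margins
plan_heel_strikes <- function(p, foot) {
  off <- if (foot == "R") 0 else 0.5 * p$t_stride
  k <- seq(-3, ceiling(p$duration / p$t_stride) + 2)
  p$t_hs0 + off + k * p$t_stride
}

# internal: foot placement x positions matching plan_heel_strikes
plan_placements <- function(p, foot) {
  hs <- plan_heel_strikes(p, foot)
  p$v * (hs - p$t_hs0) + p$land_offset
}

# internal: per-foot COP trajectory (n x 2) at times t; continuous
# heel-to-toe advance during stance, linear toe-to-next-heel during swing
plan_foot_cop <- function(p, foot, t) {
  hs <- plan_heel_strikes(p, foot)
  px <- plan_placements(p, foot)
  py <- if (foot == "R") -p$subject$step_width_m / 2 else
    p$subject$step_width_m / 2
  i <- pmax(findInterval(t, hs), 1L)
  in_stance <- t <= hs[i] + p$stance & t >= hs[i]
  s <- clip((t - hs[i]) / p$stance, 0, 1)
  x <- px[i] + p$cop_heel + (p$cop_toe - p$cop_heel) * s
  # swing: from this step's toe to the next step's heel
  to_t <- hs[i] + p$stance
  u <- clip((t - to_t) / (hs[i + 1L] - to_t), 0, 1)
  x_sw <- (px[i] + p$cop_toe) * (1 - u) + (px[i + 1L] + p$cop_heel) * u
  x[!in_stance] <- x_sw[!in_stance]
  cbind(x = x, y = rep(py, length(t)))
}

# internal: load share in [0,1] for one foot at times t (cosine ramps)
plan_foot_share <- function(p, foot, t) {
  hs <- plan_heel_strikes(p, foot)
  i <- pmax(findInterval(t, hs), 1L)
  up <- (1 - cos(pi * clip((t - hs[i]) / p$ds, 0, 1))) / 2
  dn <- (1 - cos(pi * clip((hs[i] + p$stance - t) / p$ds, 0, 1))) / 2
  share <- up * dn
  share[t > hs[i] + p$stance] <- 0
  share
}

# internal: trunk Euler angles (yaw, pitch, roll; radians) at times t.
# Pelvis rotation (yaw) and obliquity (roll) at stride frequency, anterior
# tilt (pitch, mean 5 deg) at step frequency, all phase-locked to the stride.
plan_trunk_euler <- function(p, t) {
  a <- p$subject$trunk_amp_deg * pi / 180
  tau <- t - p$t_hs0
  yaw   <- a[["rotation"]] * sin(2 * pi * p$f_stride * tau)
  roll  <- a[["obliquity"]] *
    sin(2 * pi * p$f_stride * (tau - 0.05 * p$t_stride))
  pitch <- p$tilt0 + a[["tilt"]] *
    sin(4 * pi * p$f_stride * tau + p$tilt_phase)
  cbind(yaw = yaw, pitch = pitch, roll = roll)
}

# internal: gait events inside [0, duration]
plan_events <- function(p) {
  ev <- do.call(rbind, lapply(c("R", "L"), function(foot) {
    hs <- plan_heel_strikes(p, foot)
    rbind(data.frame(time = hs, foot = foot, type = "heel_strike"),
          data.frame(time = hs + p$stance, foot = foot, type = "toe_off"))
  }))
  ev <- ev[ev$time >= 0 & ev$time <= p$duration, ]
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  structure(ev, class = c("gait_events", "data.frame"))
}

#' Decompose a whole-body COM trajectory into 15 segment trajectories
#'
#' Produces per-segment COM trajectories whose mass-weighted sum reproduces
#' the prescribed whole-body COM exactly at every frame.  Each segment gets a
#' seeded offset (a constant plus a slow sinusoid); the mass-weighted mean of
#' the offsets is subtracted per frame so the weighted recomposition is an
#' identity by construction.
#'
#' @param whole_com n x 3 matrix of whole-body COM positions (m).
#' @param fractions 15 per-segment mass fractions summing to 1 (1e-9).
#' @param seed integer seed for the offsets.
#' @param t optional time vector (s) for the sinusoidal offset component;
#'   defaults to a unit-spaced grid.
#' @param offset_scale SD (m) of the constant offset component; 0 makes all
#'   segments identical to `whole_com`.
#' @return n x 3 x 15 array of segment trajectories.
#' @export
decompose_com_to_segments <- function(whole_com, fractions, seed,
                                      t = NULL, offset_scale = 0.15) {
  whole_com <- as.matrix(whole_com)
  if (length(fractions) != 15L)
    fail("need 15 mass fractions, got %d", length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9)
    fail("mass fractions must sum to 1 (got %.12f)", sum(fractions))
  n <- nrow(whole_com)
  if (is.null(t)) t <- seq_len(n)
  with_seed(seed, {
    const <- matrix(rnorm(15 * 3, 0, offset_scale), 15, 3)
    amp   <- matrix(rnorm(15 * 3, 0, offset_scale / 3), 15, 3)
    freq  <- runif(15, 0.5, 1.5)
    phi   <- runif(15, 0, 2 * pi)
  })
  segs <- array(0, dim = c(n, 3, 15),
                dimnames = list(NULL, c("x", "y", "z"),
                                default_segment_names()))
  off <- array(0, dim = c(n, 3, 15))
  for (i in 1:15) {
    osc <- sin(2 * pi * freq[i] * t + phi[i])
    off[, , i] <- outer(osc, amp[i, ]) +
      matrix(const[i, ], n, 3, byrow = TRUE)
  }
  # remove the mass-weighted mean offset per frame and coordinate
  wmean <- matrix(0, n, 3)
  for (i in 1:15) wmean <- wmean + fractions[i] * off[, , i]
  for (i in 1:15) segs[, , i] <- whole_com + off[, , i] - wmean
  segs
}

#' Sensor motion container
#'
#' Dense position and orientation of the waist-mounted sensor, the input to
#' [synthesize_imu()].  Orientation is given as ZYX Euler angles (yaw about
#' global Z, pitch about Y, roll about X; radians) of the sensor/trunk frame
#' relative to the global frame.
#'
#' @param t strictly increasing time vector (s), regularly spaced.
#' @param pos n x 3 sensor positions (m, global frame).
#' @param euler n x 3 matrix of (yaw, pitch, roll) in radians.
#' @return object of class `sensor_motion`.
#' @export
sensor_motion <- function(t, pos, euler) {
  pos <- as.matrix(pos); euler <- as.matrix(euler)
  if (length(t) < 2L) fail("motion must span at least two samples")
  if (any(diff(t) <= 0)) fail("timestamps must be strictly increasing")
  if (nrow(pos) != length(t) || nrow(euler) != length(t))
    fail("pos/euler rows must match length(t)")
  structure(list(t = t, pos = pos, euler = euler,
                 rate = 1 / stats::median(diff(t))),
            class = "sensor_motion")
}

# internal: n x 9 rotation matrices (column-major R[,1:9] = r11,r21,r31,r12,..)
# for ZYX Euler angles; columns are the body axes expressed in global frame
euler_to_rotmat <- function(euler) {
  cy <- cos(euler[, 1]); sy <- sin(euler[, 1])
  cp <- cos(euler[, 2]); sp <- sin(euler[, 2])
  cr <- cos(euler[, 3]); sr <- sin(euler[, 3])
  cbind(cy * cp, sy * cp, -sp,
        cy * sp * sr - sy * cr, sy * sp * sr + cy * cr, cp * sr,
        cy * sp * cr + sy * sr, sy * sp * cr - cy * sr, cp * cr)
}

#' Synthesize 9-channel IMU streams from sensor motion
#'
#' Accelerometer: specific force in the sensor frame — the second derivative
#' of sensor position minus gravity, rotated into the sensor frame (central
#' finite differences on the dense motion grid).  Gyroscope: body-frame
#' angular velocity from the rotation matrices (deg/s).  Magnetometer: a
#' fixed Earth-field vector rotated into the sensor frame (uT).  White noise
#' and a random-walk drift are added per channel, and every channel is
#' clipped to the sensor ranges (+/-16 g, +/-2000 deg/s, +/-4800 uT).
#'
#' @param motion a [sensor_motion()] object; its grid should be denser than
#'   the output rate (derivatives are taken on it).
#' @param noise a [noise_spec()].
#' @param out_rate output sampling rate (Hz), default 100.
#' @param mag_field Earth magnetic field in the global frame (uT).
#' @return data.frame with columns time, ax, ay, az (m/s^2), gx, gy, gz
#'   (deg/s), mx, my, mz (uT) at `out_rate`.
#' @export
synthesize_imu <- function(motion, noise = noise_spec(), out_rate = 100,
                           mag_field = c(25, 0, -40)) {
  if (!inherits(motion, "sensor_motion")) fail("motion must be sensor_motion")
  t <- motion$t; pos <- motion$pos
  n <- length(t)
  if (n < 5L) fail("motion too short to differentiate")
  h <- (t[n] - t[1]) / (n - 1)
  R <- euler_to_rotmat(motion$euler)
  # second derivative of position (interior points)
  idx <- 2:(n - 1)
  acc_g <- (pos[idx + 1, , drop = FALSE] - 2 * pos[idx, , drop = FALSE] +
              pos[idx - 1, , drop = FALSE]) / h^2
  # specific force in global frame: a - g, g = (0,0,-9.81)
  acc_g[, 3] <- acc_g[, 3] + GRAVITY
  Ri <- R[idx, , drop = FALSE]
  rot_to_body <- function(Rm, v) {
    # body = R^T v, with R stored row-wise as 9 columns (column-major 3x3)
    cbind(Rm[, 1] * v[, 1] + Rm[, 2] * v[, 2] + Rm[, 3] * v[, 3],
          Rm[, 4] * v[, 1] + Rm[, 5] * v[, 2] + Rm[, 6] * v[, 3],
          Rm[, 7] * v[, 1] + Rm[, 8] * v[, 2] + Rm[, 9] * v[, 3])
  }
  accel <- rot_to_body(Ri, acc_g)
  # body angular velocity: skew(omega) = R^T dR/dt
  Rdot <- (R[idx + 1, , drop = FALSE] - R[idx - 1, , drop = FALSE]) / (2 * h)
  Rc <- R[idx, , drop = FALSE]
  s32 <- rowSums(Rc[, 7:9, drop = FALSE] * Rdot[, 4:6, drop = FALSE])
  s13 <- rowSums(Rc[, 1:3, drop = FALSE] * Rdot[, 7:9, drop = FALSE])
  s21 <- rowSums(Rc[, 4:6, drop = FALSE] * Rdot[, 1:3, drop = FALSE])
  gyro <- cbind(s32, s13, s21) * 180 / pi
  mag <- rot_to_body(Ri, matrix(mag_field, length(idx), 3, byrow = TRUE))
  ti <- t[idx]
  # resample onto the output grid (linear; the dense grid oversamples)
  t_out <- seq(max(0, ti[1]), ti[length(ti)], by = 1 / out_rate)
  pick <- function(col) approx(ti, col, xout = t_out)$y
  sig <- cbind(apply(accel, 2, pick), apply(gyro, 2, pick),
               apply(mag, 2, pick))
  colnames(sig) <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  m <- length(t_out)
  sig <- with_seed(noise$seed, {
    sig_ch <- rep(c(noise$accel_sigma, noise$gyro_sigma, noise$mag_sigma),
                  each = 3)
    for (j in 1:9) {
      white <- rnorm(m, 0, sig_ch[j])
      drift <- cumsum(rnorm(m, 0, sig_ch[j] * noise$drift_rate))
      sig[, j] <- sig[, j] + white + drift
    }
    sig
  })
  rng <- rep(c(16 * GRAVITY, 2000, 4800), each = 3)
  for (j in 1:9) sig[, j] <- clip(sig[, j], -rng[j], rng[j])
  data.frame(time = t_out, sig)
}

#' Simulate one walking trial
#'
#' Generates a physically consistent trial from a closed-form 3D
#' inverted-pendulum-style gait model: segment COM trajectories at the mocap
#' rate (which mass-weight back to the prescribed whole-body COM exactly),
#' per-plate vertical GRF and COP at the force-plate rate (plate 1 carries
#' the right foot, plate 2 the left, with smooth double-support load
#' transfer), 9-channel IMU streams from a sensor over L5, and the gait
#' events.  All streams share one clock starting at 0.
#'
#' @param subject a [subject_params()] object.
#' @param speed_class one of "slow", "normal", "fast".
#' @param seed integer; together with the subject it fully determines the
#'   trial, including the IMU noise realization.
#' @param noise a [noise_spec()]; its own seed is ignored and re-derived from
#'   `seed` so one trial seed fixes everything.
#' @param duration trial length (s); must allow >= 1 full gait cycle.
#' @param trial_id optional identifier stored in the metadata.
#' @return object of class `trial_recording`.
#' @export
simulate_trial <- function(subject, speed_class, seed,
                           noise = noise_spec(), duration = 6,
                           trial_id = NA_integer_) {
  if (!inherits(subject, "subject_params")) fail("subject must be subject_params")
  if (!speed_class %in% c("slow", "normal", "fast"))
    fail("unknown speed_class '%s': must be slow, normal or fast",
         as.character(speed_class))
  seed <- as.integer(seed)
  p <- gait_plan(subject, speed_class, derive_seed(seed, "plan"), duration)

  mocap_rate <- 120; force_rate <- 1080; imu_rate <- 100
  t_mocap <- seq(0, duration, by = 1 / mocap_rate)
  t_force <- seq(0, duration, by = 1 / force_rate)

  whole <- plan_com(p, t_mocap)
  fr <- default_mass_fractions()
  segs <- decompose_com_to_segments(whole, fr, derive_seed(seed, "segments"),
                                    t = t_mocap)

  f_total <- subject$mass_kg * (GRAVITY + plan_com_zacc(p, t_force))
  share_r <- plan_foot_share(p, "R", t_force)
  share_l <- plan_foot_share(p, "L", t_force)
  tot <- share_r + share_l
  tot[tot <= 0] <- 1
  grf <- list(t = t_force,
              fz1 = f_total * share_r / tot,
              fz2 = f_total * share_l / tot,
              cop1 = plan_foot_cop(p, "R", t_force),
              cop2 = plan_foot_cop(p, "L", t_force))

  # dense sensor motion (600 Hz, extended so central differences cover the
  # full [0, duration] interval), sensor offset from COM in the trunk frame
  dense_rate <- 600
  t_dense <- seq(-3 / dense_rate, duration + 3 / dense_rate,
                 by = 1 / dense_rate)
  euler <- plan_trunk_euler(p, t_dense)
  Rd <- euler_to_rotmat(euler)
  r_off <- c(-0.10, 0, 0.05) # posterior of and slightly above the COM (L5)
  com_d <- plan_com(p, t_dense)
  pos <- com_d + cbind(Rd[, 1] * r_off[1] + Rd[, 4] * r_off[2] + Rd[, 7] * r_off[3],
                       Rd[, 2] * r_off[1] + Rd[, 5] * r_off[2] + Rd[, 8] * r_off[3],
                       Rd[, 3] * r_off[1] + Rd[, 6] * r_off[2] + Rd[, 9] * r_off[3])
  motion <- sensor_motion(t_dense, pos, euler)
  ns <- noise_spec(noise$accel_sigma, noise$gyro_sigma, noise$mag_sigma,
                   noise$drift_rate, seed = derive_seed(seed, "imu_noise"))
  imu <- synthesize_imu(motion, ns, out_rate = imu_rate)
  imu <- imu[imu$time <= duration + 1e-9, ]

  events <- plan_events(p)

  trial <- structure(list(
    subject_id = subject$subject_id, speed_class = speed_class,
    mocap_rate = mocap_rate, force_rate = force_rate, imu_rate = imu_rate,
    t_mocap = t_mocap, segment_coms = segs, grf = grf, imu = imu,
    events = events,
    meta = list(trial_id = trial_id, seed = seed, mass_kg = subject$mass_kg,
                com_height_m = subject$com_height_m,
                stride_time_s = p$t_stride, step_length_m = p$step_length,
                speed_mps = p$v, t_hs0 = p$t_hs0, noise = ns,
                subject = subject)),
    class = "trial_recording")
  validate_trial_recording(trial)
  trial
}

# internal: structural invariants of a trial
validate_trial_recording <- function(x) {
  stopifnot(inherits(x, "trial_recording"))
  if (dim(x$segment_coms)[3] != 15L) fail("need exactly 15 segment trajectories")
  if (any(diff(x$t_mocap) <= 0) || any(diff(x$grf$t) <= 0) ||
      any(diff(x$imu$time) <= 0))
    fail("timestamps must be strictly increasing")
  if (any(x$grf$fz1 < -1e-9) || any(x$grf$fz2 < -1e-9))
    fail("vertical GRF must be nonnegative")
  hs <- x$events[x$events$type == "heel_strike", ]
  if (nrow(hs) < 3L) fail("trial too short: fewer than one analyzable cycle")
  if (any(hs$foot[-1] == hs$foot[-nrow(hs)]))
    fail("heel strikes must alternate feet")
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s %s: %.1f s, %d mocap frames, %d force samples, %d IMU samples, %d events\n",
    x$subject_id, x$speed_class, max(x$t_mocap), length(x$t_mocap),
    length(x$grf$t), nrow(x$imu), nrow(x$events)))
  invisible(x)
}
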