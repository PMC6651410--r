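test_that("subject sampling is seeded, population-faithful and clipped", {
  expect_identical(sample_subject(7), sample_subject(7))
  hts <- vapply(1:1000, function(k) sample_subject(k)$height_cm, numeric(1))
  expect_lt(abs(mean(hts) - 171.2), 0.5)
  expect_true(all(hts >= 171.2 - 3 * 4.3 & hts <= 171.2 + 3 * 4.3))
  s <- sample_subject(3)
  expect_lt(s$leg_length_m, s$height_cm / 100)
  expect_true(s$speed_scalars[["slow"]] < 1 && s$speed_scalars[["fast"]] > 1)
})

test_that("trial simulation is deterministic and rejects bad speed classes", {
  s <- fixture_subject()
  expect_identical(simulate_trial(s, "slow", seed = 5),
                   simulate_trial(s, "slow", seed = 5))
  expect_error(simulate_trial(s, "sprint", seed = 1), "unknown speed_class")
})

test_that("vertical GRF is nonnegative and balances body weight over a stride", {
  tr <- simulate_trial(fixture_subject(), "normal", seed = 3,
                       noise = noise_spec(0, 0, 0, 0))
  g <- tr$grf
  expect_true(all(g$fz1 >= 0) && all(g$fz2 >= 0))
  # support never vanishes
  expect_true(all(g$fz1 + g$fz2 > 0))
  # impulse-momentum: mean total vertical force over one stride = m g (2%)
  t0 <- tr$meta$t_hs0
  sel <- g$t >= t0 & g$t < t0 + tr$meta$stride_time_s
  ratio <- mean(g$fz1[sel] + g$fz2[sel]) / (tr$meta$mass_kg * 9.81)
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("ground-truth inclination angles respect the physiological envelopes", {
  for (k in 1:2) {
    s <- sample_subject(200 + k)
    for (sp in c("slow", "normal", "fast")) {
      ia <- trial_inclination_angles(simulate_trial(s, sp, seed = 30 + k))$ia
      expect_true(all(abs(ia$sagittal) <= 20),
                  label = sprintf("sagittal envelope (%s, seed %d)", sp, k))
      expect_true(all(abs(ia$frontal) <= 10),
                  label = sprintf("frontal envelope (%s, seed %d)", sp, k))
    }
  }
})

test_that("mean forward COM speed orders slow < normal < fast", {
  s <- fixture_subject()
  v <- vapply(c("slow", "normal", "fast"), function(sp) {
    tr <- simulate_trial(s, sp, seed = 9)
    com <- whole_body_com(tr$segment_coms)
    diff(range(com[, 1])) / diff(range(tr$t_mocap))
  }, numeric(1))
  expect_true(v[["slow"]] < v[["normal"]] && v[["normal"]] < v[["fast"]])
})

test_that("segment decomposition recomposes to the whole-body COM exactly", {
  fr <- default_mass_fractions()
  whole <- cbind(seq(0, 2, length.out = 50), sin(1:50 / 5), rep(0.9, 50))
  segs <- decompose_com_to_segments(whole, fr, seed = 4)
  expect_lt(max(abs(whole_body_com(segs) - whole)), 1e-9)
  # zero-offset request: all segments identical to the whole-body COM
  segs0 <- decompose_com_to_segments(whole, fr, seed = 4, offset_scale = 0)
  for (i in 1:15) expect_lt(max(abs(segs0[, , i] - whole)), 1e-12)
  # mass-weighted offsets sum to zero per frame (direct summation oracle)
  off <- sweep(matrix(0, 50, 3), 1, 0)
  for (i in 1:15) off <- off + fr[i] * (segs[, , i] - whole)
  expect_lt(max(abs(off)), 1e-9)
  expect_error(decompose_com_to_segments(whole, fr[1:14], seed = 1), "15")
  expect_error(decompose_com_to_segments(whole, fr * 1.1, seed = 1), "sum to 1")
})

test_that("IMU synthesis reproduces statics, analytic dynamics and sensor ranges", {
  # stationary upright trunk: pure gravity, zero rotation, the Earth field
  n <- 60; t <- seq(0, 1, length.out = n)
  still <- sensor_motion(t, matrix(rep(c(0, 0, 1), each = n), n, 3),
                         matrix(0, n, 3))
  imu <- synthesize_imu(still, noise_spec(0, 0, 0, 0),
                        mag_field = c(25, 0, -40))
  expect_lt(max(abs(imu$ax), abs(imu$ay), abs(imu$az - 9.81)), 1e-6)
  expect_lt(max(abs(imu[, c("gx", "gy", "gz")])), 1e-6)
  expect_lt(max(abs(imu$mx - 25), abs(imu$my), abs(imu$mz + 40)), 1e-9)

  # analytic oracle: sinusoidal sway, fixed orientation
  td <- seq(-0.01, 2.01, by = 1 / 600)
  A <- 0.05; f <- 1.2
  pos <- cbind(A * sin(2 * pi * f * td), 0 * td, 1 + 0 * td)
  imu2 <- synthesize_imu(sensor_motion(td, pos, matrix(0, length(td), 3)),
                         noise_spec(0, 0, 0, 0))
  ax_true <- -A * (2 * pi * f)^2 * sin(2 * pi * f * imu2$time)
  expect_lt(max(abs(imu2$ax - ax_true)), 1e-3)

  # analytic oracle: constant spin about the vertical axis
  w <- 1.5 # rad/s
  spin <- sensor_motion(td, matrix(0, length(td), 3),
                        cbind(w * td, 0 * td, 0 * td))
  imu3 <- synthesize_imu(spin, noise_spec(0, 0, 0, 0))
  expect_lt(max(abs(imu3$gz - w * 180 / pi)), 1e-3)
  expect_lt(max(abs(imu3[, c("gx", "gy")])), 1e-3)

  # range clipping on every generated channel
  tr <- fixture_trial()
  rng <- rep(c(16 * 9.81, 2000, 4800), each = 3)
  chans <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  for (j in seq_along(chans))
    expect_true(all(abs(tr$imu[[chans[j]]]) <= rng[j]))
})

test_that("gait events alternate feet and support at least one cycle", {
  tr <- fixture_trial()
  hs <- tr$events[tr$events$type == "heel_strike", ]
  expect_true(all(hs$foot[-1] != hs$foot[-nrow(hs)]))
  cyc <- segment_gait_cycle(tr$events)
  expect_gte(nrow(cyc), 1)
  # each foot's heel strike precedes its own toe-off within a stance
  for (ft in c("R", "L")) {
    h <- tr$events$time[tr$events$foot == ft & tr$events$type == "heel_strike"]
    to <- tr$events$time[tr$events$foot == ft & tr$events$type == "toe_off"]
    expect_true(all(vapply(h, function(x) any(to > x), logical(1))[-length(h)]))
  }
})
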