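test_that("whole-body COM is the mass-weighted segment mean", {
  n <- 20
  p <- c(0.3, -0.1, 0.9)
  segs <- array(rep(p, each = n), dim = c(n, 3, 15))
  expect_equal(whole_body_com(segs),
               matrix(p, n, 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z"))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # two-point toy folded into 15 slots: 0.6 at origin, 0.4 at (1,0,0)
  fr <- c(0.6, 0.4, rep(1e-13, 13))
  segs2 <- array(0, dim = c(1, 3, 15))
  segs2[1, 1, 2] <- 1
  m <- anthropometric_model(fr / 1) # sums to 1 within 1e-9
  expect_equal(unname(whole_body_com(segs2, m)[1, ]), c(0.4, 0, 0),
               tolerance = 1e-10)
  expect_error(whole_body_com(array(0, dim = c(5, 3, 14))), "15")
})

test_that("net COP is the force-weighted convex combination of plate COPs", {
  c1 <- cbind(rep(0, 4), rep(0, 4))
  c2 <- cbind(rep(0.4, 4), rep(0.1, 4))
  # equal loads: midpoint
  eq <- net_cop(c1, c2, rep(300, 4), rep(300, 4))
  expect_equal(unname(eq[1, ]), c(0.2, 0.05), tolerance = 1e-12)
  # single support: the loaded plate's COP
  ss <- net_cop(c1, c2, rep(500, 4), rep(0, 4))
  expect_equal(unname(ss[1, ]), c(0, 0), tolerance = 1e-12)
  # hand-computed weighted mean: 600 N at (0,0), 200 N at (0.4, 0.1)
  h <- net_cop(c1, c2, rep(600, 4), rep(200, 4))
  expect_equal(unname(h[1, ]), c(0.1, 0.025), tolerance = 1e-12)
  # convexity on random inputs
  withr::with_seed(1, {
    f1 <- runif(200, 0, 800); f2 <- runif(200, 0, 800)
    p1 <- cbind(runif(200, -1, 1), runif(200, -1, 1))
    p2 <- cbind(runif(200, -1, 1), runif(200, -1, 1))
  })
  nc <- net_cop(p1, p2, f1, f2)
  lo <- pmin(p1, p2) - 1e-12; hi <- pmax(p1, p2) + 1e-12
  expect_true(all(nc >= lo & nc <= hi))
  # zero total force flags the frame
  expect_warning(z <- net_cop(c1, c2, rep(0, 4), rep(0, 4)), "zero total")
  expect_true(all(attr(z, "invalid")))
})

test_that("inclination angles follow the COP-to-COM cross-product definition", {
  # COM directly above COP
  ia0 <- inclination_angles(cbind(0, 0, 1), cbind(0, 0))
  expect_equal(c(ia0$sagittal, ia0$frontal), c(0, 0), tolerance = 1e-12)
  # anterior offset only: sagittal = asin(0.1 / sqrt(1.01)), frontal = 0
  ia1 <- inclination_angles(cbind(0.1, 0, 1), cbind(0, 0))
  expect_equal(ia1$sagittal, asin(0.1 / sqrt(1.01)) * 180 / pi,
               tolerance = 1e-9)
  expect_lt(abs(ia1$sagittal - 5.710), 1e-3)
  expect_equal(ia1$frontal, 0, tolerance = 1e-12)
  # symmetric lateral case
  ia2 <- inclination_angles(cbind(0, 0.1, 1), cbind(0, 0))
  expect_equal(ia2$frontal, ia1$sagittal, tolerance = 1e-9)
  expect_equal(ia2$sagittal, 0, tolerance = 1e-12)
  # scale invariance of the angle
  ia3 <- inclination_angles(cbind(0.03, -0.02, 0.97) * 7,
                            cbind(0, 0))
  ia4 <- inclination_angles(cbind(0.03, -0.02, 0.97), cbind(0, 0))
  expect_equal(as.matrix(ia3), as.matrix(ia4), tolerance = 1e-9)
  expect_error(inclination_angles(cbind(0, 0, -1), cbind(0, 0)), "positive")
})

test_that("gait-cycle segmentation implements both window policies", {
  ev <- data.frame(time = c(0.0, 0.12, 0.62, 0.72, 1.1),
                   foot = c("R", "L", "L", "R", "R"),
                   type = c("heel_strike", "toe_off", "heel_strike",
                            "toe_off", "heel_strike"))
  pm <- segment_gait_cycle(ev, "paper_modified")
  expect_equal(unlist(pm[1, c("start", "end")]), c(start = 0.12, end = 0.62))
  st <- segment_gait_cycle(ev, "standard")
  expect_equal(unlist(st[1, c("start", "end")]), c(start = 0.0, end = 1.1))
  expect_true(all(pm$end > pm$start))
  expect_error(segment_gait_cycle(ev[1, ]), "insufficient")
})

test_that("time normalization preserves endpoints and analytic shapes", {
  expect_equal(time_normalize(rep(2.5, 30), 100), rep(2.5, 100))
  ramp <- time_normalize(seq(1, 4, length.out = 57), 100)
  expect_equal(ramp, seq(1, 4, length.out = 100), tolerance = 1e-12)
  t120 <- seq(0, 1, length.out = 120)
  y <- time_normalize(sin(2 * pi * t120), 100, t = t120)
  expect_lt(max(abs(y - sin(2 * pi * seq(0, 1, length.out = 100)))), 1e-3)
  expect_error(time_normalize(1, 100), "at least 2")
})

test_that("pure-plane COM offsets decouple (zero cross-plane angle)", {
  n <- 50
  sag <- inclination_angles(cbind(seq(-0.2, 0.2, length.out = n), 0, 1),
                            cbind(rep(0, n), rep(0, n)))
  expect_true(all(abs(sag$frontal) < 1e-9))
  fro <- inclination_angles(cbind(0, seq(-0.1, 0.1, length.out = n), 1),
                            cbind(rep(0, n), rep(0, n)))
  expect_true(all(abs(fro$sagittal) < 1e-9))
})
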