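force_df <- function(Fx = 0, Fy = 0, Fz = -700, Mx = 0, My = 0, Mz = 0,
                     n = 5, rate = 100) {
  df <- data.frame(t = (seq_len(n) - 1) / rate, Fx = Fx, Fy = Fy, Fz = Fz,
                   Mx = Mx, My = My, Mz = Mz)
  attr(df, "sample_rate") <- rate
  df
}

test_that("COP follows the force-plate formula", {
  cop <- compute_cop(force_df())
  expect_true(all(cop == 0))

  cop2 <- compute_cop(force_df(My = 35))
  expect_equal(unname(cop2[1, "x"]), 0.05)
  cop3 <- compute_cop(force_df(Mx = 35))
  expect_equal(unname(cop3[1, "y"]), -0.05)

  # the plate-surface offset couples shear into the COP
  cop4 <- compute_cop(force_df(Fx = 70, My = 35), d_z = 0.1)
  expect_equal(unname(cop4[1, "x"]), (-35 - 70 * 0.1) / -700)

  expect_error(compute_cop(force_df(Fz = -10)), "unloaded")
})

test_that("the foot rectangle is frame-invariant and noise-stable", {
  tpl <- body_template()
  zero <- joint_angle_tensor(matrix(0, 30, 12), 100)
  mk <- forward_kinematics(zero, tpl)
  b <- foot_boundary(marker_xyz(mk, "mt1"), marker_xyz(mk, "mt5"),
                     marker_xyz(mk, "toe"), marker_xyz(mk, "cal"))
  expect_equal(diff(b$ml_range), 0.10, tolerance = 1e-9)
  expect_equal(diff(b$ap_range), 0.25, tolerance = 1e-9)

  # rotate the foot 30 degrees about vertical: foot-frame extents unchanged
  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot_marker <- function(m) m %*% t(Rz)
  b2 <- foot_boundary(rot_marker(marker_xyz(mk, "mt1")),
                      rot_marker(marker_xyz(mk, "mt5")),
                      rot_marker(marker_xyz(mk, "toe")),
                      rot_marker(marker_xyz(mk, "cal")))
  expect_equal(b2$ml_range, b$ml_range, tolerance = 1e-9)
  expect_equal(b2$ap_range, b$ap_range, tolerance = 1e-9)

  # 1 mm marker jitter moves the extents by < 2 mm
  withr::local_seed(12)
  jit <- function(m) m + rnorm(length(m), 0, 1e-3)
  b3 <- foot_boundary(jit(marker_xyz(mk, "mt1")), jit(marker_xyz(mk, "mt5")),
                      jit(marker_xyz(mk, "toe")), jit(marker_xyz(mk, "cal")))
  expect_lt(abs(diff(b3$ml_range) - 0.10), 2e-3)

  same <- marker_xyz(mk, "cal")
  expect_error(foot_boundary(same, same, same, same), "degenerate axis")
})

test_that("TTB matches the per-sample formula and its brute force", {
  # constant velocity: distance / speed
  rate <- 100
  p <- 0 + 0.02 * (0:99) / rate          # v = +0.02 m/s from the centre
  s <- ttb_ml(p, c(-0.05, 0.05), sample_rate = rate)
  expect_equal(s$ttb[50], (0.05 - p[50]) / 0.02, tolerance = 1e-12)

  # v = 0 everywhere: all samples capped and invalid
  s0 <- ttb_ml(rep(0.01, 50), c(-0.05, 0.05), sample_rate = rate)
  expect_true(all(!s0$valid))
  expect_true(all(s0$ttb == s0$cap))

  # brute force agreement on a smooth bounded trajectory
  withr::local_seed(13)
  t <- (0:499) / rate
  p <- 0.03 * sin(2 * pi * 0.4 * t) + 0.01 * sin(2 * pi * 1.3 * t + 1)
  s1 <- ttb_ml(p, c(-0.05, 0.05), sample_rate = rate)
  v <- numeric(500)
  v[1] <- (p[2] - p[1]) * rate
  v[500] <- (p[500] - p[499]) * rate
  v[2:499] <- (p[3:500] - p[1:498]) * rate / 2
  for (i in seq_along(p)) {
    if (abs(v[i]) < 1e-6) {
      expect_false(s1$valid[i])
    } else {
      ref <- if (v[i] > 0) (0.05 - p[i]) / v[i] else (p[i] + 0.05) / -v[i]
      expect_equal(s1$ttb[i], max(ref, 0), tolerance = 1e-12)
    }
  }
})

test_that("TTB summaries follow the minima rules", {
  ser <- structure(list(ttb = c(3, 1, 3, 2, 0.5, 2), valid = rep(TRUE, 6),
                        outside = rep(FALSE, 6), cap = 10, sample_rate = 100),
                   class = "ttb_series")
  su <- ttb_summary(ser)
  expect_equal(su$mean_of_minima, 0.75)
  expect_equal(su$absolute_minimum, 0.5)
  expect_equal(su$sd_of_minima, sd(c(1, 0.5)))
  expect_equal(su$n_minima, 2L)

  # plateaus count once
  pl <- ser; pl$ttb <- c(3, 1, 1, 1, 3, 2, 0.5, 2)
  pl$valid <- pl$outside <- rep(TRUE, 8); pl$outside[] <- FALSE
  sp <- ttb_summary(pl)
  expect_equal(sp$n_minima, 2L)
  expect_equal(sp$mean_of_minima, 0.75)

  # monotone series: degenerate, absolute minimum is the last valid sample
  mono <- ser; mono$ttb <- c(5, 4, 3, 2, 1, 0.5)
  sm <- ttb_summary(mono)
  expect_true(sm$degenerate)
  expect_equal(sm$absolute_minimum, 0.5)
  expect_true(is.na(sm$mean_of_minima))

  # capped samples split the series into runs; minima only within runs
  iv <- ser
  iv$ttb <- c(3, 1, 3, 10, 3, 0.5, 2, 10, 4, 2, 3)
  iv$valid <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                TRUE, TRUE)
  iv$outside <- rep(FALSE, 11)
  si <- ttb_summary(iv)
  expect_equal(si$n_minima, 3L)
  expect_equal(sort(c(1, 0.5, 2)), sort(c(1, 0.5, 2)))
  expect_equal(si$mean_of_minima, mean(c(1, 0.5, 2)))
})

test_that("time-rescaling the COP divides TTB summaries by the factor", {
  withr::local_seed(14)
  t <- (0:799) / 100
  p <- 0.025 * sin(2 * pi * 0.35 * t) + 0.008 * sin(2 * pi * 1.1 * t + 0.5)
  k <- 2.5
  s1 <- ttb_summary(ttb_ml(p, c(-0.05, 0.05), sample_rate = 100))
  s2 <- ttb_summary(ttb_ml(p, c(-0.05, 0.05), sample_rate = 100 * k))
  expect_equal(s2$mean_of_minima, s1$mean_of_minima / k, tolerance = 1e-12)
  expect_equal(s2$absolute_minimum, s1$absolute_minimum / k,
               tolerance = 1e-12)
  expect_equal(s2$sd_of_minima, s1$sd_of_minima / k, tolerance = 1e-12)
})

test_that("TTB is invariant to rigid translation of COP and boundary", {
  withr::local_seed(15)
  t <- (0:499) / 100
  p <- 0.02 * sin(2 * pi * 0.5 * t)
  a <- ttb_summary(ttb_ml(p, c(-0.05, 0.05), sample_rate = 100))
  b <- ttb_summary(ttb_ml(p + 0.3, c(-0.05, 0.05) + 0.3, sample_rate = 100))
  expect_equal(a$mean_of_minima, b$mean_of_minima, tolerance = 1e-12)
  expect_equal(a$absolute_minimum, b$absolute_minimum, tolerance = 1e-12)
})

test_that("sway summaries match their geometric definitions", {
  still <- sway_summary(matrix(0.01, 50, 2), sample_rate = 100)
  expect_equal(still$sd_amp, 0)
  expect_equal(still$sway_velocity, 0)

  # constant-speed circle (3 full cycles): constant amplitude, velocity
  # approaches the speed as the rate grows
  rate <- 1000
  t <- (0:9999) / rate
  r <- 0.03; speed <- r * 2 * pi * 3 / 10
  th <- speed / r * t
  circ <- sway_summary(cbind(r * cos(th), r * sin(th)), sample_rate = rate)
  expect_lt(circ$sd_amp, 1e-9)
  expect_equal(circ$sway_velocity, speed, tolerance = 1e-4)

  # unit-speed straight line over 10 s
  line <- sway_summary(cbind((0:1000) / 100, 0), sample_rate = 100)
  expect_equal(line$sway_velocity, 1)
})
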