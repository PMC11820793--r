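prof <- subject_profile(1.73, 60.6)

test_that("a zero-amplitude noiseless preset is exactly static", {
  p <- motion_preset("A_quiet", duration = 5, ap_amp_mm = 0, ml_amp_mm = 0,
                     wobble_deg = 0)
  tr <- generate_trial(p, prof, accel_kind = "kinematic")
  expect_equal(tr$plate$force[, 3],
               rep(tr$profile$mass * tr$params$g, length(tr$time)),
               tolerance = 1e-9)
  expect_lt(max(abs(tr$plate$force[, 1:2])), 1e-9)
  for (s in tr$imu) expect_lt(max(abs(s$specific_force)), 1e-9)
  expect_lt(max(abs(diff(tr$truth$com$X_b))), 1e-15)
  expect_lt(max(abs(diff(tr$truth$com$Y_b))), 1e-15)
})

test_that("trials are bit-identical under a fixed seed", {
  p <- motion_preset("A_quiet", duration = 4, seed = 77)
  t1 <- generate_trial(p, prof, noise = noise_spec())
  t2 <- generate_trial(p, prof, noise = noise_spec())
  expect_identical(t1$plate$force, t2$plate$force)
  expect_identical(t1$imu$head$specific_force, t2$imu$head$specific_force)
  expect_identical(t1$imu$lower_leg$angular_velocity,
                   t2$imu$lower_leg$angular_velocity)

  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  write_trial_bundle(t1, d1)
  write_trial_bundle(t2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground-truth COM equals an independently composed kinematic chain", {
  p <- motion_preset("C_yaw", duration = 3, seed = 6)
  tr <- generate_trial(p, prof)
  pa <- tr$params
  sw <- 1   # stance right: swing hip on the +Y side
  for (k in c(1, 57, 200)) {
    segs <- tr$truth$segments
    chain <- function(seg) euler_to_matrix(seg$psi[k], seg$theta[k],
                                           seg$phi[k])
    ankle <- c(0, 0, pa$L_f)
    P <- ankle + chain(segs$m1$motion) %*% c(0, 0, pa$L_m1)
    Q <- P + c(0, sw * pa$w, 0)
    c_m1 <- ankle + chain(segs$m1$motion) %*% c(0, 0, pa$l_m1)
    c_m2 <- P + chain(segs$m2$motion) %*% c(0, 0, pa$l_m2)
    c_s1 <- Q + chain(segs$s1$motion) %*% c(0, 0, -(pa$L_s1 - pa$l_s1))
    knee <- Q + chain(segs$s1$motion) %*% c(0, 0, -pa$L_s1)
    c_s2 <- knee + chain(segs$s2$motion) %*% c(0, 0, -(pa$L_s2 - pa$l_s2))
    com <- (pa$m_m1 * c_m1 + pa$m_m2 * c_m2 + pa$m_s1 * c_s1 +
              pa$m_s2 * c_s2) /
      (pa$m_m1 + pa$m_m2 + pa$m_s1 + pa$m_s2)
    expect_equal(tr$truth$com$X_b[k], com[1], tolerance = 1e-12)
    expect_equal(tr$truth$com$Y_b[k], com[2], tolerance = 1e-12)
  }
})

test_that("mirrored preset negates the lateral ground truth", {
  mk <- function(side, ph) generate_trial(
    motion_preset("A_quiet", duration = 6, seed = 3, stance_side = side,
                  ml_phase = ph, wobble_deg = 0),
    subject_profile(1.73, 60.6, side))
  t_r <- mk("right", c(0.9, 2.1))
  t_l <- mk("left", c(0.9, 2.1) + pi)
  expect_lt(max(abs(t_r$truth$com$Y_b + t_l$truth$com$Y_b)), 1e-12)
  expect_lt(max(abs(t_r$truth$com$X_b - t_l$truth$com$X_b)), 1e-12)
})

test_that("condition B oscillates the vertical hip load about the static
           weight with zero mean over whole cycles", {
  tr <- cached("trialB20", generate_trial(
    motion_preset("B_updown", duration = 20, seed = 4), prof))
  static_w <- -(tr$params$m_s1 + tr$params$m_s2) * tr$params$g
  # 12 whole cycles at 0.75 Hz, starting after the ramp
  w <- which(tr$time >= 4 & tr$time < 4 + 12 / 0.75)
  dev <- tr$truth$hip$R_s[w, 3] - static_w
  expect_gt(sd(dev), 1)                    # the load genuinely oscillates
  expect_lt(abs(mean(dev)), 0.02 * sd(dev))
  spec <- Mod(fft(dev))[-1]
  peak <- which.max(spec[1:(length(dev) / 2)])
  f_peak <- peak / (length(dev) / tr$fs)
  expect_equal(f_peak, 0.75, tolerance = 0.05)
})

test_that("estimator error grows monotonically with sensor noise", {
  p <- motion_preset("A_quiet", duration = 20, seed = 12)
  w <- 501:1900
  rmse_at <- function(scale) {
    noise <- if (scale == 0) NULL else
      noise_spec(accel_sd = 0.02 * scale, gyro_sd = 0.2 * pi / 180 * scale,
                 force_sd = 0.5 * scale, moment_sd = 0.1 * scale)
    tr <- generate_trial(p, prof, noise = noise)
    est <- estimate_trial(tr)
    gt <- ground_truth_com(tr)
    rmse_mm(est$com$X_b, gt$X_b, w) + rmse_mm(est$com$Y_b, gt$Y_b, w)
  }
  errs <- vapply(c(0, 1, 4), rmse_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("presets violating the small-angle regime are rejected", {
  p <- motion_preset("A_quiet", ap_amp_mm = c(120, 0))
  expect_error(generate_trial(p, prof), "5 deg")
})

test_that("both emitted acceleration conventions recover the same motion", {
  # pins down the gravity handling: specific force is the kinematic
  # acceleration minus gravity in the sensor frame, so after the transform
  # (which removes gravity for specific-force input only) both conventions
  # must yield identical stationary-frame accelerations
  p <- motion_preset("B_updown", duration = 6, seed = 2)
  t_sf <- generate_trial(p, prof, accel_kind = "specific_force")
  t_kin <- generate_trial(p, prof, accel_kind = "kinematic")
  s1 <- t_sf$truth$segments$s1$motion
  att <- attitude_series(s1$psi, s1$theta, s1$phi, t_sf$fs)
  a_sf <- transform_accel(t_sf$imu$thigh, att, input = "specific_force")
  a_kin <- transform_accel(t_kin$imu$thigh, att, input = "kinematic")
  expect_equal(a_sf, a_kin, tolerance = 1e-9)
  expect_lt(max(abs(a_sf - t_sf$truth$segments$s1$com$acc)), 1e-9)
})
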