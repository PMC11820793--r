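g <- 9.80665
fs <- 100

test_that("3-2-1 rotation matrices are orthonormal and act as expected", {
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
  expect_equal(as.numeric(euler_to_matrix(pi / 2, 0, 0) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:300) {
    ang <- runif(3, -pi, pi)
    Tm <- euler_to_matrix(ang[1], ang[2], ang[3])
    expect_lt(max(abs(t(Tm) %*% Tm - diag(3))), 1e-12)
    expect_equal(det(Tm), 1, tolerance = 1e-12)
  }
  # composition: yaw then pitch then roll about moving axes
  ang <- c(0.4, -0.3, 0.7)
  Rz <- euler_to_matrix(ang[1], 0, 0)
  Ry <- euler_to_matrix(0, ang[2], 0)
  Rx <- euler_to_matrix(0, 0, ang[3])
  expect_equal(euler_to_matrix(ang[1], ang[2], ang[3]), Rz %*% Ry %*% Rx,
               tolerance = 1e-14)
})

test_that("attitude series stores matrices consistent with its angles", {
  att <- attitude_series(c(0.1, 0.2), c(-0.3, 0.05), c(0.6, -0.2), fs)
  for (k in 1:2) {
    expect_lt(max(abs(att$T[, , k] -
                        euler_to_matrix(att$psi[k], att$theta[k],
                                        att$phi[k]))), 1e-12)
  }
})

static_imu <- function(theta, phi, n, placement = "thigh") {
  Tm <- euler_to_matrix(0, theta, phi)
  f <- matrix(rep(as.numeric(t(Tm) %*% c(0, 0, g)), n), n, 3, byrow = TRUE)
  imu_series((0:(n - 1)) / fs, f, matrix(0, n, 3), placement)
}

test_that("roll/pitch EKF recovers static tilts", {
  rp <- estimate_roll_pitch(static_imu(0, 0, 200))
  expect_lt(max(abs(rp$theta)), 1e-10)
  expect_lt(max(abs(rp$phi)), 1e-10)

  rp <- estimate_roll_pitch(static_imu(5 * pi / 180, -3 * pi / 180, 300))
  after_1s <- 101:300
  expect_lt(max(abs(rp$theta[after_1s] - 5 * pi / 180)), 1e-3)
  expect_lt(max(abs(rp$phi[after_1s] + 3 * pi / 180)), 1e-3)
})

test_that("roll/pitch EKF tracks a sinusoidal tilt of a pivoting sensor", {
  # sensor at the rotation axis: the accelerometer sees pure gravity
  n <- 2000
  t <- (0:(n - 1)) / fs
  theta <- 2 * pi / 180 * sin(2 * pi * 0.3 * t)
  rate <- 2 * pi / 180 * 2 * pi * 0.3 * cos(2 * pi * 0.3 * t)
  f <- t(vapply(seq_len(n),
                function(k) as.numeric(t(euler_to_matrix(0, theta[k], 0)) %*%
                                         c(0, 0, g)),
                numeric(3)))
  w <- cbind(0, rate, 0)
  imu <- imu_series(t, f, w, "thigh")
  rp <- estimate_roll_pitch(imu)
  expect_lt(sqrt(mean((rp$theta[200:n] - theta[200:n])^2)), 0.2 * pi / 180)
})

test_that("free-fall-like samples are flagged and bridged by the gyro", {
  n <- 200
  f <- matrix(0, n, 3)           # near-zero specific force
  f[1:50, 3] <- g                # level start so the filter initialises
  imu <- imu_series((0:(n - 1)) / fs, f, matrix(0, n, 3), "thigh")
  rp <- estimate_roll_pitch(imu)
  expect_true(all(rp$low_obs[51:n]))
  expect_false(any(rp$low_obs[1:50]))
  expect_lt(max(abs(rp$theta)), 1e-8)   # gyro-only prediction holds the state
})

test_that("yaw integration shares the vertical rate and starts at zero", {
  n <- 1001
  t <- (0:(n - 1)) / fs
  mk <- function(wz, placement) {
    imu_series(t, matrix(rep(c(0, 0, g), n), n, 3, byrow = TRUE),
               cbind(0, 0, wz), placement)
  }
  rp0 <- list(theta = rep(0, n), phi = rep(0, n))
  out <- integrate_yaw(mk(rep(0, n), "thigh"), mk(rep(0, n), "lower_leg"),
                       rp0, rp0)
  expect_equal(out$psi_s1, rep(0, n))

  out <- integrate_yaw(mk(rep(0.1, n), "thigh"), mk(rep(0.1, n), "lower_leg"),
                       rp0, rp0)
  expect_equal(out$psi_s1[1], 0)
  expect_equal(out$psi_s1[n], 1.0, tolerance = 1e-12)
  expect_identical(out$psi_s1, out$psi_s2)

  # equal true rates plus independent noise: shared output, O(sigma sqrt(n))
  set.seed(9)
  s_t <- 0.5 * sin(2 * pi * 0.4 * t)
  truth <- cumsum(c(0, s_t[-n])) / fs
  o <- integrate_yaw(mk(s_t + rnorm(n, 0, 0.01), "thigh"),
                     mk(s_t + rnorm(n, 0, 0.01), "lower_leg"), rp0, rp0)
  expect_identical(o$psi_s1, o$psi_s2)
  expect_lt(max(abs(o$psi_s1 - truth)), 0.01 * sqrt(n) / fs * 5)
})

test_that("yaw drift under zero-mean rate noise grows as sigma*sqrt(n)/fs", {
  n <- 2000
  sigma <- 0.01
  rp0 <- list(theta = rep(0, n), phi = rep(0, n))
  t <- (0:(n - 1)) / fs
  f <- matrix(rep(c(0, 0, g), n), n, 3, byrow = TRUE)
  set.seed(21)
  final <- replicate(40, {
    a <- imu_series(t, f, cbind(0, 0, rnorm(n, 0, sigma)), "thigh")
    b <- imu_series(t, f, cbind(0, 0, rnorm(n, 0, sigma)), "lower_leg")
    integrate_yaw(a, b, rp0, rp0)$psi_s1[n]
  })
  # averaging two independent sensors halves the rate variance
  theory <- sigma * sqrt(n / 2) / fs
  expect_gt(sd(final), theory / 1.7)
  expect_lt(sd(final), theory * 1.7)
})

test_that("acceleration transform removes gravity at any attitude", {
  n <- 50
  t <- (0:(n - 1)) / fs
  ang <- c(0.5, -0.4, 0.9)
  Tm <- euler_to_matrix(ang[1], ang[2], ang[3])
  f <- matrix(rep(as.numeric(t(Tm) %*% c(0, 0, g)), n), n, 3, byrow = TRUE)
  imu <- imu_series(t, f, matrix(0, n, 3), "thigh")
  att <- attitude_series(rep(ang[1], n), rep(ang[2], n), rep(ang[3], n), fs)
  a <- transform_accel(imu, att)
  expect_lt(max(abs(a)), 1e-12)

  ff <- imu_series(t, matrix(0, n, 3), matrix(0, n, 3), "thigh")
  a <- transform_accel(ff, att)
  expect_equal(a[1, ], c(0, 0, -g))
})

test_that("transformed accelerations match the analytic segment motion", {
  tr <- cached("trialB12", generate_trial(
    motion_preset("B_updown", duration = 12, seed = 4), default_profile()))
  s1 <- tr$truth$segments$s1$motion
  att <- attitude_series(s1$psi, s1$theta, s1$phi, fs)
  a <- transform_accel(tr$imu$thigh, att)
  expect_lt(max(abs(a - tr$truth$segments$s1$com$acc)), 1e-3)
})
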