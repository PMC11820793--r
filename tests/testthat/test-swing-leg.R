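fs <- 100
pa <- compute_body_params(subject_profile(1.73, 60.6))

const_att <- function(psi, theta, phi, n = 5) {
  attitude_series(rep(psi, n), rep(theta, n), rep(phi, n), fs)
}

test_that("segment COMs follow the rigid-link geometry", {
  n <- 5
  down <- const_att(0, 0, 0, n)
  sc <- segment_coms(down, down, pa)
  expect_equal(sc$r_s1[1, ], c(0, 0, -(pa$L_s1 - pa$l_s1)))
  expect_equal(sc$r_s2[1, ], c(0, 0, -pa$L_s1 - (pa$L_s2 - pa$l_s2)))

  # thigh horizontal (pitched forward by 90 deg), shank vertical
  horiz <- const_att(0, -pi / 2, 0, n)
  sc <- segment_coms(horiz, down, pa)
  expect_equal(sc$r_s1[1, 3], 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(sc$r_s1[1, ]^2)), pa$L_s1 - pa$l_s1,
               tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    a1 <- const_att(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    a2 <- const_att(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    sc <- segment_coms(a1, a2, pa)
    expect_lt(max(abs(pa$m_s1 * sc$r_s1 + pa$m_s2 * sc$r_s2 -
                        (pa$m_s1 + pa$m_s2) * sc$r_s)), 1e-12)
  }
})

static_hip <- function(att1, att2) {
  n <- length(att1$theta)
  z <- matrix(0, n, 3)
  coms <- segment_coms(att1, att2, pa)
  hip_load(att1, att2, z, z, z, z, coms, pa, fs)
}

test_that("a static leg transmits its weight, and zero moment when vertical", {
  down <- const_att(0, 0, 0, 10)
  hl <- static_hip(down, down)
  expect_equal(hl$R_s[1, ], c(0, 0, -(pa$m_s1 + pa$m_s2) * pa$g),
               tolerance = 1e-12)
  expect_lt(max(abs(hl$N_s)), 1e-12)
})

test_that("a hanging tilted static leg produces weight-times-offset moment", {
  a1 <- const_att(0, -0.4, 0, 10)   # thigh pitched forward
  a2 <- const_att(0, -0.1, 0, 10)
  hl <- static_hip(a1, a2)
  coms <- segment_coms(a1, a2, pa)
  expect_equal(hl$N_s[1, 2],
               pa$g * (pa$m_s1 * coms$r_s1[1, 1] +
                         pa$m_s2 * coms$r_s2[1, 1]),
               tolerance = 1e-10)
  expect_equal(hl$N_s[1, 1],
               -pa$g * (pa$m_s1 * coms$r_s1[1, 2] +
                          pa$m_s2 * coms$r_s2[1, 2]),
               tolerance = 1e-10)
})

test_that("inverse dynamics matches the analytic hip wrench on a swing trial", {
  tr <- cached("trialB12", generate_trial(
    motion_preset("B_updown", duration = 12, seed = 4), default_profile()))
  s1 <- tr$truth$segments$s1$motion
  s2 <- tr$truth$segments$s2$motion
  att1 <- attitude_series(s1$psi, s1$theta, s1$phi, fs)
  att2 <- attitude_series(s2$psi, s2$theta, s2$phi, fs)
  coms <- segment_coms(att1, att2, tr$params)
  hl <- hip_load(att1, att2,
                 tr$truth$segments$s1$com$acc, tr$truth$segments$s2$com$acc,
                 tr$imu$thigh$angular_velocity,
                 tr$imu$lower_leg$angular_velocity,
                 coms, tr$params, fs)
  expect_lt(max(abs(hl$R_s - tr$truth$hip$R_s)), 0.1)
  expect_lt(max(abs(hl$N_s - tr$truth$hip$N_s)), 0.01)
})

test_that("hip loads are linear in the segment masses", {
  tr <- cached("trialB12", generate_trial(
    motion_preset("B_updown", duration = 12, seed = 4), default_profile()))
  s1 <- tr$truth$segments$s1$motion
  s2 <- tr$truth$segments$s2$motion
  att1 <- attitude_series(s1$psi, s1$theta, s1$phi, fs)
  att2 <- attitude_series(s2$psi, s2$theta, s2$phi, fs)
  acc1 <- tr$truth$segments$s1$com$acc
  acc2 <- tr$truth$segments$s2$com$acc
  gy1 <- tr$imu$thigh$angular_velocity
  gy2 <- tr$imu$lower_leg$angular_velocity
  coms <- segment_coms(att1, att2, tr$params)
  hl1 <- hip_load(att1, att2, acc1, acc2, gy1, gy2, coms, tr$params, fs)
  p2 <- tr$params
  for (f in c("m_s1", "m_s2", "J_s1x", "J_s1y", "J_s1z",
              "J_s2x", "J_s2y", "J_s2z")) p2[[f]] <- 3 * p2[[f]]
  hl3 <- hip_load(att1, att2, acc1, acc2, gy1, gy2, coms, p2, fs)
  expect_equal(hl3$R_s, 3 * hl1$R_s, tolerance = 1e-12)
  expect_equal(hl3$N_s, 3 * hl1$N_s, tolerance = 1e-12)
})

test_that("rotating all inputs by a fixed yaw rotates the hip wrench", {
  tr <- cached("trialB12", generate_trial(
    motion_preset("B_updown", duration = 12, seed = 4), default_profile()))
  s1 <- tr$truth$segments$s1$motion
  s2 <- tr$truth$segments$s2$motion
  att1 <- attitude_series(s1$psi, s1$theta, s1$phi, fs)
  att2 <- attitude_series(s2$psi, s2$theta, s2$phi, fs)
  acc1 <- tr$truth$segments$s1$com$acc
  acc2 <- tr$truth$segments$s2$com$acc
  gy1 <- tr$imu$thigh$angular_velocity
  gy2 <- tr$imu$lower_leg$angular_velocity
  coms <- segment_coms(att1, att2, tr$params)
  hl <- hip_load(att1, att2, acc1, acc2, gy1, gy2, coms, tr$params, fs)

  dpsi <- 0.8
  Rz <- euler_to_matrix(dpsi, 0, 0)
  att1r <- attitude_series(s1$psi + dpsi, s1$theta, s1$phi, fs)
  att2r <- attitude_series(s2$psi + dpsi, s2$theta, s2$phi, fs)
  comsr <- segment_coms(att1r, att2r, tr$params)
  hlr <- hip_load(att1r, att2r, acc1 %*% t(Rz), acc2 %*% t(Rz),
                  gy1, gy2, comsr, tr$params, fs)
  expect_equal(hlr$R_s, hl$R_s %*% t(Rz), tolerance = 1e-9)
  expect_equal(hlr$N_s, hl$N_s %*% t(Rz), tolerance = 1e-9)
})

test_that("non-uniform sampling and length mismatches are rejected", {
  expect_error(imu_series(c(0, 0.01, 0.5), matrix(0, 3, 3) + c(0, 0, 9.8),
                          matrix(0, 3, 3), "thigh"), "uniform")
  a5 <- const_att(0, 0, 0, 5)
  a6 <- const_att(0, 0, 0, 6)
  expect_error(segment_coms(a5, a6, pa), "disagree")
})
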