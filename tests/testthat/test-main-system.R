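fs <- 100
pa <- compute_body_params(subject_profile(1.73, 60.6))

static_hip_series <- function(n, Rsz = -(pa$m_s1 + pa$m_s2) * pa$g) {
  z <- matrix(0, n, 3)
  f <- z; f[, 3] <- Rsz
  structure(list(R_s = f, N_s = z), class = "hip_load_series")
}

quiet_plate <- function(n, Fz = 594) {
  force_plate_series((0:(n - 1)) / fs,
                     cbind(0, 0, rep(Fz, n)), matrix(0, n, 3))
}

test_that("all-zero dynamic inputs give the zero solution", {
  n <- 20
  sol <- solve_sagittal(quiet_plate(n), static_hip_series(n), rep(0, n), pa)
  expect_equal(sol$X_m, rep(0, n))
  expect_equal(sol$acc_m1, rep(0, n))
  expect_equal(sol$acc_m2, rep(0, n))
  expect_false(any(sol$flagged))
})

test_that("coefficients match their closed forms and are logged per solve", {
  n <- 4
  hip <- static_hip_series(n)
  sol <- solve_sagittal(quiet_plate(n), hip, rep(0, n), pa)
  expect_equal(sol$A22, -pa$J_m2y / pa$l_m2 -
                 pa$m_m2 * (pa$L_f + pa$L_m1 + pa$l_m2), tolerance = 1e-12)
  expect_equal(sol$A23[1],
               ((pa$m_m1 + pa$m_m2) * pa$g - hip$R_s[1, 3]) *
                 pa$L_m1 / pa$l_m, tolerance = 1e-12)
  fro <- solve_frontal(quiet_plate(n), hip, rep(0, n), pa, "right")
  expect_equal(fro$B21, pa$J_m1x / pa$l_m1 +
                 pa$m_m1 * (pa$L_f + pa$l_m1) -
                 pa$J_m2x * pa$L_m1 / (pa$l_m1 * pa$l_m2), tolerance = 1e-12)
  expect_equal(fro$B23, -sol$A23, tolerance = 1e-12)
})

test_that("a static tilted pose is recovered to well under 0.1 mm", {
  tr <- cached("static10", generate_trial(static_preset(), default_profile()))
  est <- cached("static10_est", estimate_trial(tr))
  gt <- ground_truth_com(tr)
  k <- 301:900
  expect_lt(max(abs(est$com$X_b[k] - gt$X_b[k])), 1e-4)
  expect_lt(max(abs(est$com$Y_b[k] - gt$Y_b[k])), 1e-4)
})

test_that("per-sample back-substitution residuals stay below 1e-9", {
  tr <- cached("trialA12", generate_trial(
    motion_preset("A_quiet", duration = 12, seed = 1), default_profile()))
  est <- cached("trialA12_est", estimate_trial(tr))
  expect_lt(max(est$main$sagittal$residual), 1e-9)
  expect_lt(max(est$main$frontal$residual), 1e-9)
  expect_false(any(est$main$sagittal$flagged))
})

test_that("singular samples are flagged and held at the previous solution", {
  n <- 30
  hip <- static_hip_series(n)
  hip$R_s[, 1] <- 1          # small constant shear so the solution is nonzero
  hip$R_s[20, 3] <- (pa$m_m1 + pa$m_m2) * pa$g   # makes A23 exactly zero
  sol <- solve_sagittal(quiet_plate(n), hip, rep(0, n), pa)
  expect_true(sol$flagged[20])
  expect_equal(sol$X_m[20], sol$X_m[19])
  expect_false(any(sol$flagged[-20]))
})

test_that("frontal solution mirrors exactly under stance-side flip", {
  pr <- function(side, ph) motion_preset(
    "A_quiet", duration = 12, seed = 5, stance_side = side,
    ml_phase = ph, wobble_deg = 0)
  t_r <- generate_trial(pr("right", c(0.9, 2.1)), default_profile("right"))
  t_l <- generate_trial(pr("left", c(0.9, 2.1) + pi), default_profile("left"))
  e_r <- estimate_trial(t_r)
  e_l <- estimate_trial(t_l)
  expect_lt(max(abs(e_r$com$Y_b + e_l$com$Y_b)), 1e-9)
  expect_lt(max(abs(e_r$com$X_b - e_l$com$X_b)), 1e-9)
  expect_lt(max(abs(t_r$truth$com$Y_b + t_l$truth$com$Y_b)), 1e-12)
})
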