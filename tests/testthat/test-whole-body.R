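fs <- 100
pa <- compute_body_params(subject_profile(1.73, 60.6))

test_that("COM fusion follows the mass-weighted arithmetic", {
  n <- 4
  main <- list(X_m = rep(0.004, n), Y_m = rep(-0.002, n))
  sub <- list(r_s = cbind(rep(0, n), 0, -0.5))
  out <- combine_com(main, sub, pa, "right")
  m_main <- pa$m_m1 + pa$m_m2
  m_sub <- pa$m_s1 + pa$m_s2
  m_eff <- m_main + m_sub
  expect_equal(out$X_b, rep(m_main * 0.004 / m_eff, n))
  expect_equal(out$Y_b, rep((m_main * -0.002 + m_sub * pa$w) / m_eff, n))

  # static vertical leg below the swing hip, centred main system
  main0 <- list(X_m = rep(0, n), Y_m = rep(0, n))
  out <- combine_com(main0, sub, pa, "right")
  expect_equal(out$Y_b, rep(m_sub * pa$w / m_eff, n))
  out_l <- combine_com(main0, sub, pa, "left")
  expect_equal(out_l$Y_b, -out$Y_b)

  # degenerate subsystem mass: fused COM reduces to the main system
  p0 <- pa
  p0$m_s1 <- 1e-12
  p0$m_s2 <- 1e-12
  out <- combine_com(main, sub, p0, "right")
  expect_equal(out$X_b, main$X_m, tolerance = 1e-10)
  expect_equal(out$Y_b, main$Y_m, tolerance = 1e-10)
})

test_that("fusion is exact when the subsystem sits on the main-system COM", {
  n <- 6
  main <- list(X_m = seq(0, 0.005, length.out = n),
               Y_m = seq(-0.003, 0.002, length.out = n))
  sub <- list(r_s = cbind(main$X_m, main$Y_m - pa$w, -0.4))
  out <- combine_com(main, sub, pa, "right")
  expect_equal(out$X_b, main$X_m, tolerance = 1e-12)
  expect_equal(out$Y_b, main$Y_m, tolerance = 1e-12)
})

test_that("COP follows plate statics and masks unloaded samples", {
  n <- 5
  d <- 0.03
  F <- 600
  plate <- force_plate_series((0:(n - 1)) / fs,
                              cbind(0, 0, rep(F, n)),
                              cbind(0, rep(-F * d, n), 0))
  cop <- compute_cop(plate)
  expect_equal(cop$COP_X, rep(d, n))
  expect_equal(cop$COP_Y, rep(0, n))

  plate$force[3, 3] <- 10    # below threshold
  cop <- compute_cop(plate, fz_min = 50)
  expect_true(is.na(cop$COP_X[3]))
  expect_false(anyNA(cop$COP_X[-3]))

  # sensor plane below the surface shifts COP by the shear lever
  plate2 <- force_plate_series((0:(n - 1)) / fs,
                               cbind(rep(20, n), 0, rep(F, n)),
                               cbind(0, rep(-F * d, n), 0))
  cop2 <- compute_cop(plate2, h = 0.01)
  expect_equal(cop2$COP_X, rep(d - 20 * 0.01 / F, n))
})

test_that("static synthetic trial has COP on the ground-truth COM", {
  tr <- cached("static10", generate_trial(static_preset(), default_profile()))
  cop <- compute_cop(tr$plate)
  gt <- ground_truth_com(tr)
  expect_lt(max(abs(cop$COP_X - gt$X_b)), 1e-6)
  expect_lt(max(abs(cop$COP_Y - gt$Y_b)), 1e-6)
})

test_that("agreement metrics reproduce their defining formulas", {
  set.seed(8)
  ref <- sin(2 * pi * 0.3 * (0:4499) / fs) * 0.006
  m <- com_metrics(ref, ref)
  expect_equal(m$r, 1)
  expect_equal(m$rmse, 0)

  m <- com_metrics(ref + 0.001, ref)
  expect_equal(m$rmse, 0.001, tolerance = 1e-12)
  expect_equal(m$r, 1, tolerance = 1e-12)

  # r is invariant under affine rescaling; RMSE is translation-covariant
  est <- ref + rnorm(4500, 0, 5e-4)
  m1 <- com_metrics(est, ref)
  m2 <- com_metrics(3 * est + 0.01, ref)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  expect_equal(m1$rms_ref, sqrt(mean((ref[1001:4000] -
                                        mean(ref[1001:4000]))^2)))
  expect_equal(m1$rmse_rms_ratio, m1$rmse / m1$rms_ref)

  expect_warning(mc <- com_metrics(est, rep(0.001, 4500)), "constant")
  expect_true(is.na(mc$r))
  expect_gt(mc$rmse, 0)

  expect_error(com_metrics(est[1:100], ref[1:100]), "window")
  expect_error(com_metrics(est[1:100], ref), "lengths")
})
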