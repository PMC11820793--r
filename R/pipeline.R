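# End-to-end estimation pipeline: attitudes -> gravity-free accelerations ->
# swing-leg COM and hip wrench -> drift-filtered plate forces -> per-sample
# plane solves -> whole-body COM fusion -> zero-phase smoothing of COM and
# COP.

#' Estimator configuration
#'
#' All free tunables of the pipeline with their defaults: the
#' roll/pitch EKF noise scales, the 0.1 Hz drift high-pass for the
#' horizontal plate forces, the 3 Hz smoothing low-pass for COM and COP,
#' the evaluation window, the solve condition-number gate, the COP
#' threshold, and optional fixed sensor-to-segment mounting rotations.
#'
#' @param g Gravitational acceleration \[m/s^2\].
#' @param ekf An [ekf_config()].
#' @param hp [filter_spec()] for the horizontal plate forces.
#' @param lp [filter_spec()] for the estimated COM and COP.
#' @param window Length-2 integer vector, first and last sample of the
#'   evaluation window.
#' @param cond_threshold Condition-number gate of the per-sample solves.
#' @param accel_input What the IMU acceleration channels contain:
#'   `"specific_force"` (gravity included; the hardware convention) or
#'   `"kinematic"`.
#' @param gyro_filter Optional [filter_spec()] applied to the gyro series
#'   before differentiation in the inverse dynamics.
#' @param cop_h Plate sensor-plane depth \[m\].
#' @param cop_fz_min Minimum vertical load \[N\] for a defined COP.
#' @param mount_rotation Optional named list (`head`, `thigh`, `lower_leg`)
#'   of 3x3 sensor-to-segment rotation matrices; `NULL` entries mean the
#'   sensor axes coincide with the segment axes.
#'
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(g = 9.80665,
                             ekf = ekf_config(),
                             hp = filter_spec("highpass", 0.1, 4),
                             lp = filter_spec("lowpass", 3, 4),
                             window = c(1001L, 4000L),
                             cond_threshold = 1e10,
                             accel_input = c("specific_force", "kinematic"),
                             gyro_filter = NULL,
                             cop_h = 0, cop_fz_min = 50,
                             mount_rotation = list()) {
  accel_input <- match.arg(accel_input)
  structure(list(g = g, ekf = ekf, hp = hp, lp = lp,
                 window = as.integer(window),
                 cond_threshold = cond_threshold,
                 accel_input = accel_input, gyro_filter = gyro_filter,
                 cop_h = cop_h, cop_fz_min = cop_fz_min,
                 mount_rotation = mount_rotation),
            class = "estimator_config")
}

# Expected kinematic acceleration at the two swing-leg sensors, predicted
# from the gyro rates and the rigid-link geometry (sensors at segment COM
# height; hip joint Q quasi-stationary). For a point at fixed offset s from
# its pivot the world acceleration is wdot x s + w x (w x s); the knee's
# acceleration (from the thigh) seeds the lower-leg sensor. Returned in each
# sensor's frame, for use as the EKF's `accel_comp`.
predict_sensor_accel <- function(att_thigh, att_lower, gyro_thigh,
                                 gyro_lower, params, fs) {
  n <- dim(att_thigh$T)[3]
  one <- matrix(1, n, 1)
  w1 <- rotate_rows(att_thigh$T, gyro_thigh)
  w2 <- rotate_rows(att_lower$T, gyro_lower)
  wd1 <- differentiate(w1, fs)
  wd2 <- differentiate(w2, fs)
  point_acc <- function(w, wd, s) {
    cross_rows(wd, s) + cross_rows(w, cross_rows(w, s))
  }
  s_thigh <- rotate_rows(att_thigh$T,
                         one %*% c(0, 0, -(params$L_s1 - params$l_s1)))
  s_knee <- rotate_rows(att_thigh$T, one %*% c(0, 0, -params$L_s1))
  s_shank <- rotate_rows(att_lower$T,
                         one %*% c(0, 0, -(params$L_s2 - params$l_s2)))
  a_thigh <- point_acc(w1, wd1, s_thigh)
  a_shank <- point_acc(w1, wd1, s_knee) + point_acc(w2, wd2, s_shank)
  list(thigh = rotate_rows(att_thigh$T, a_thigh, transpose = TRUE),
       lower_leg = rotate_rows(att_lower$T, a_shank, transpose = TRUE))
}

apply_mount <- function(imu, R_off) {
  if (is.null(R_off)) return(imu)
  n <- nrow(imu$specific_force)
  Rarr <- array(R_off, dim = c(3, 3, n))
  imu$specific_force <- rotate_rows(Rarr, imu$specific_force)
  imu$angular_velocity <- rotate_rows(Rarr, imu$angular_velocity)
  imu
}

#' Estimate the whole-body COM from plate and IMU series
#'
#' Runs the full pipeline: roll/pitch EKF per sensor, shared-rate yaw
#' integration for the swing-leg sensors (head yaw held at zero),
#' gravity-removed stationary-frame accelerations, swing-leg segment COMs
#' and hip wrench by inverse dynamics, 0.1 Hz zero-phase high-pass on the
#' horizontal plate forces, per-sample sagittal and frontal solves,
#' whole-body COM fusion, COP computation and 3 Hz zero-phase smoothing of
#' both.
#'
#' @param plate A [force_plate_series()].
#' @param imu_head,imu_thigh,imu_lower [imu_series()] for the three sensors;
#'   they are matched by their `placement` field, so argument order need not
#'   follow the physical placement.
#' @param profile A [subject_profile()].
#' @param config An [estimator_config()].
#'
#' @return An object of class `com_estimate`: smoothed `com` and `cop`, the
#'   unsmoothed `com_raw`/`cop_raw`, the `main` solution (with coefficient
#'   records and per-sample residuals), hip loads, subsystem COMs, attitude
#'   series, the parameters used and a `log` of pipeline stages.
#' @export
estimate_com <- function(plate, imu_head, imu_thigh, imu_lower, profile,
                         config = estimator_config()) {
  stopifnot(inherits(plate, "force_plate_series"))
  imus <- list(imu_head, imu_thigh, imu_lower)
  placements <- vapply(imus, function(x) x$placement, character(1))
  if (!setequal(placements, c("head", "thigh", "lower_leg"))) {
    stop("need exactly one IMU for each of head, thigh, lower_leg; got: ",
         paste(placements, collapse = ", "), call. = FALSE)
  }
  names(imus) <- placements
  imus <- lapply(stats::setNames(nm = c("head", "thigh", "lower_leg")),
                 function(nm) apply_mount(imus[[nm]],
                                          config$mount_rotation[[nm]]))
  n <- nrow(plate$force)
  fs <- plate$fs
  if (any(vapply(imus, function(x) nrow(x$specific_force), 0L) != n)) {
    stop("plate and IMU series lengths disagree", call. = FALSE)
  }
  params <- compute_body_params(profile, config$g)
  log <- sprintf("input: %d samples at %.6g Hz, stance side %s",
                 n, fs, profile$stance_side)

  # unit sanity: vertical load should be about body weight
  med_rz <- stats::median(plate$force[, 3])
  m_mov <- params$m_m1 + params$m_m2 + params$m_s1 + params$m_s2 + params$m_f
  if (med_rz < 0.5 * m_mov * params$g || med_rz > 1.5 * m_mov * params$g) {
    warning(sprintf(
      "median vertical load %.1f N is far from body weight %.1f N; check units",
      med_rz, m_mov * params$g), call. = FALSE)
  }

  # pass 1: gravity-referenced EKF; pass 2 re-runs the swing-leg filters
  # with the lever-arm acceleration predicted from pass-1 attitudes removed
  # from the gravity measurement (the swing leg is a pendulum with a known
  # geometry, so its motion-induced acceleration is predictable)
  rp <- lapply(imus, estimate_roll_pitch, config = config$ekf, g = config$g)
  yaw <- integrate_yaw(imus$thigh, imus$lower_leg, rp$thigh, rp$lower_leg)
  att1_thigh <- attitude_series(yaw$psi_s1, rp$thigh$theta, rp$thigh$phi, fs)
  att1_lower <- attitude_series(yaw$psi_s2, rp$lower_leg$theta,
                                rp$lower_leg$phi, fs)
  comp <- predict_sensor_accel(att1_thigh, att1_lower,
                               imus$thigh$angular_velocity,
                               imus$lower_leg$angular_velocity, params, fs)
  rp$thigh <- estimate_roll_pitch(imus$thigh, config$ekf, config$g,
                                  accel_comp = comp$thigh)
  rp$lower_leg <- estimate_roll_pitch(imus$lower_leg, config$ekf, config$g,
                                      accel_comp = comp$lower_leg)
  yaw <- integrate_yaw(imus$thigh, imus$lower_leg, rp$thigh, rp$lower_leg)
  att <- list(
    head = attitude_series(0, rp$head$theta, rp$head$phi, fs),
    thigh = attitude_series(yaw$psi_s1, rp$thigh$theta, rp$thigh$phi, fs),
    lower_leg = attitude_series(yaw$psi_s2, rp$lower_leg$theta,
                                rp$lower_leg$phi, fs)
  )
  low_obs <- vapply(rp, function(x) sum(x$low_obs), 0L)
  log <- c(log, sprintf(
    "attitude: low-observability samples head %d, thigh %d, lower %d",
    low_obs[["head"]], low_obs[["thigh"]], low_obs[["lower_leg"]]))

  acc <- lapply(stats::setNames(nm = c("head", "thigh", "lower_leg")),
                function(nm) transform_accel(imus[[nm]], att[[nm]],
                                             g = config$g,
                                             input = config$accel_input))

  sub <- segment_coms(att$thigh, att$lower_leg, params)
  hip <- hip_load(att$thigh, att$lower_leg, acc$thigh, acc$lower_leg,
                  imus$thigh$angular_velocity,
                  imus$lower_leg$angular_velocity,
                  sub, params, fs, gyro_filter = config$gyro_filter)
  log <- c(log, sprintf(
    "hip load: mean R_sz %.2f N (static reference %.2f N)",
    mean(hip$R_s[, 3]), -(params$m_s1 + params$m_s2) * params$g))

  plate_f <- plate
  plate_f$force[, 1] <- zero_phase_filter(plate$force[, 1], config$hp, fs)
  plate_f$force[, 2] <- zero_phase_filter(plate$force[, 2], config$hp, fs)

  main <- solve_main(plate_f, hip, acc$head, params, profile$stance_side,
                     config$cond_threshold)
  log <- c(log, sprintf(
    "solve: A21 %.4g A22 %.4g A23[1] %.4g | B21 %.4g B22 %.4g B23[1] %.4g",
    main$sagittal$A21, main$sagittal$A22, main$sagittal$A23[1],
    main$frontal$B21, main$frontal$B22, main$frontal$B23[1]))
  log <- c(log, sprintf(
    "solve: flagged samples sagittal %d, frontal %d; max residual %.3g",
    sum(main$sagittal$flagged), sum(main$frontal$flagged),
    max(main$sagittal$residual, main$frontal$residual)))

  com_raw <- combine_com(main, sub, params, profile$stance_side)
  cop_raw <- compute_cop(plate, h = config$cop_h, fz_min = config$cop_fz_min)

  com <- com_series(zero_phase_filter(com_raw$X_b, config$lp, fs),
                    zero_phase_filter(com_raw$Y_b, config$lp, fs))
  cop <- cop_raw
  if (!anyNA(cop_raw$COP_X)) {
    cop <- structure(
      list(COP_X = zero_phase_filter(cop_raw$COP_X, config$lp, fs),
           COP_Y = zero_phase_filter(cop_raw$COP_Y, config$lp, fs)),
      class = "cop_series")
  } else {
    log <- c(log, "cop: masked samples present, smoothing skipped")
  }
  log <- c(log, "output: COM and COP smoothed (zero-phase low-pass)")

  structure(list(time = plate$time, fs = fs, com = com, com_raw = com_raw,
                 cop = cop, cop_raw = cop_raw, main = main, hip = hip,
                 sub = sub, attitude = att, params = params,
                 config = config, log = log),
            class = "com_estimate")
}

#' @export
print.com_estimate <- function(x, ...) {
  cat("COM estimate\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Validate a COM estimate against a reference series
#'
#' Computes per-plane agreement metrics ([com_metrics()]) between the
#' smoothed COM estimate and a reference COM (e.g. optical motion capture or
#' synthetic ground truth) over the evaluation window.
#'
#' @param est A [estimate_com()] result, or a [com_series()].
#' @param reference A [com_series()] (or list with `X_b`, `Y_b` in metres).
#' @param window Evaluation window (sample indices); defaults to the
#'   estimator config's window for a `com_estimate`, else samples 1001-4000.
#'
#' @return List with `metrics_report`s `ap` and `ml`.
#' @export
validate_estimate <- function(est, reference, window = NULL) {
  com <- if (inherits(est, "com_estimate")) est$com else est
  if (is.null(window)) {
    window <- if (inherits(est, "com_estimate")) {
      seq(est$config$window[1], est$config$window[2])
    } else 1001:4000
  }
  list(ap = com_metrics(com$X_b, reference$X_b, window),
       ml = com_metrics(com$Y_b, reference$Y_b, window))
}

#' Estimate a synthetic trial with its own bundled inputs
#'
#' Convenience wrapper: runs [estimate_com()] on the plate and IMU streams
#' of a [generate_trial()] result, declaring the trial's acceleration
#' convention to the estimator.
#'
#' @param trial A [generate_trial()] result.
#' @param config An [estimator_config()]; its `accel_input` is overridden by
#'   the trial's `accel_kind`.
#'
#' @return A `com_estimate`.
#' @export
estimate_trial <- function(trial, config = estimator_config()) {
  stopifnot(inherits(trial, "synthetic_trial"))
  config$accel_input <- trial$accel_kind
  estimate_com(trial$plate, trial$imu$head, trial$imu$thigh,
               trial$imu$lower_leg, trial$profile, config)
}
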