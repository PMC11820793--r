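# Per-sample attitude estimation for the three IMUs. Roll and pitch come
# from a two-state extended Kalman filter driven by the gyroscope with the
# accelerometer's gravity direction as measurement; yaw of the two swing-leg
# sensors is a forward-Euler integral of their shared vertical angular rate
# (no magnetometer). The head sensor's yaw is held at zero (head facing
# forward, and head yaw is unobservable without a magnetometer).

#' IMU time series
#'
#' Container for one inertial measurement unit's synchronized tri-axial
#' specific force and angular velocity, both expressed in the sensor frame.
#'
#' @param time Sample times \[s\], uniformly spaced.
#' @param specific_force n x 3 matrix \[m/s^2\]. By convention this is the
#'   accelerometer reading `f = T' (a - g_vec)` (kinematic acceleration minus
#'   gravity, rotated into the sensor frame); a stationary level sensor reads
#'   `(0, 0, +g)`.
#' @param angular_velocity n x 3 matrix \[rad/s\], sensor frame.
#' @param placement One of `"head"`, `"thigh"`, `"lower_leg"`.
#'
#' @return An object of class `imu_series` with elements `time`, `fs`,
#'   `specific_force`, `angular_velocity`, `placement`.
#' @export
imu_series <- function(time, specific_force, angular_velocity,
                       placement = c("head", "thigh", "lower_leg")) {
  placement <- match.arg(placement)
  specific_force <- unname(as.matrix(specific_force))
  angular_velocity <- unname(as.matrix(angular_velocity))
  n <- length(time)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  if (nrow(specific_force) != n || nrow(angular_velocity) != n ||
      ncol(specific_force) != 3L || ncol(angular_velocity) != 3L) {
    stop("channel lengths disagree: expected n x 3 matrices matching 'time'",
         call. = FALSE)
  }
  if (!all(is.finite(specific_force)) || !all(is.finite(angular_velocity))) {
    stop("IMU channels contain non-finite values", call. = FALSE)
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("sampling is not uniform", call. = FALSE)
  }
  structure(list(time = as.numeric(time), fs = 1 / dt[1],
                 specific_force = specific_force,
                 angular_velocity = angular_velocity,
                 placement = placement),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("IMU series (%s): %d samples at %.6g Hz\n",
              x$placement, length(x$time), x$fs))
  invisible(x)
}

#' Attitude filter configuration
#'
#' Tunables of the roll/pitch extended Kalman filter. The accelerometer's
#' effective measurement noise is `sqrt(accel_noise^2 + accel_dynamic_sd^2)`:
#' during limb motion the accelerometer senses kinematic acceleration on top
#' of gravity, so its usefulness as a tilt reference is limited by motion
#' magnitude rather than by sensor noise. `accel_dynamic_sd` sets that scale.
#'
#' @param gyro_noise Gyroscope rate noise density \[rad/s/sqrt(Hz)\].
#' @param accel_noise Accelerometer noise \[m/s^2\].
#' @param accel_dynamic_sd Expected kinematic-acceleration disturbance
#'   \[m/s^2\] treated as additional measurement noise.
#' @param init_cov Initial state covariance \[rad^2\] (diagonal).
#' @param obs_gate Relative gate on the specific-force norm: samples with
#'   `abs(|f| - g) > obs_gate * g` (free-fall-like or strongly accelerated)
#'   are flagged low-observability and processed by gyro prediction only.
#'
#' @return An object of class `ekf_config`.
#' @export
ekf_config <- function(gyro_noise = 0.005, accel_noise = 0.05,
                       accel_dynamic_sd = 3.0, init_cov = 0.1,
                       obs_gate = 0.5) {
  structure(list(gyro_noise = gyro_noise, accel_noise = accel_noise,
                 accel_dynamic_sd = accel_dynamic_sd, init_cov = init_cov,
                 obs_gate = obs_gate),
            class = "ekf_config")
}

#' Estimate roll and pitch with an extended Kalman filter
#'
#' Two-state EKF on (roll, pitch). The process model integrates the Euler
#' angle kinematics with the measured body rates; the measurement model is
#' the gravity direction seen by the accelerometer. The state is initialised
#' from the first accelerometer sample. Samples whose specific-force norm is
#' far from g (see [ekf_config()]) are flagged and bridged by gyro
#' prediction alone.
#'
#' @param imu An [imu_series()].
#' @param config An [ekf_config()].
#' @param g Gravitational acceleration \[m/s^2\].
#' @param accel_comp Optional n x 3 matrix of the sensor's expected
#'   kinematic acceleration in the sensor frame (e.g. the lever-arm
#'   acceleration of a sensor mounted on a swinging segment, predicted from
#'   the gyro rates). It is subtracted from the specific force before the
#'   gravity-direction update, removing the motion-induced bias of the tilt
#'   measurement.
#'
#' @return A list with numeric vectors `theta` (pitch), `phi` (roll) \[rad\]
#'   and a logical vector `low_obs` flagging gyro-only samples.
#' @export
estimate_roll_pitch <- function(imu, config = ekf_config(), g = 9.80665,
                                accel_comp = NULL) {
  stopifnot(inherits(imu, "imu_series"))
  f <- imu$specific_force
  if (!is.null(accel_comp)) {
    stopifnot(nrow(accel_comp) == nrow(f))
    f <- f - accel_comp
  }
  w <- imu$angular_velocity
  n <- nrow(f)
  dt <- 1 / imu$fs
  theta <- numeric(n)
  phi <- numeric(n)
  low_obs <- logical(n)

  # init from the first accelerometer sample (gravity-consistent tilt)
  phi0 <- atan2(f[1, 2], f[1, 3])
  theta0 <- atan2(-f[1, 1], sqrt(f[1, 2]^2 + f[1, 3]^2))
  x <- c(phi0, theta0)
  P <- diag(config$init_cov, 2)
  Q <- diag(config$gyro_noise^2 * dt, 2)
  Rm <- diag(config$accel_noise^2 + config$accel_dynamic_sd^2, 3)
  I2 <- diag(2)

  for (k in seq_len(n)) {
    if (k > 1L) {
      p <- w[k - 1L, 1]; q <- w[k - 1L, 2]; r <- w[k - 1L, 3]
      sph <- sin(x[1]); cph <- cos(x[1])
      tth <- tan(x[2]); cth2 <- cos(x[2])^2
      phidot <- p + tth * (q * sph + r * cph)
      thetadot <- q * cph - r * sph
      Fj <- matrix(c(
        tth * (q * cph - r * sph), (q * sph + r * cph) / cth2,
        -q * sph - r * cph,        0
      ), 2, 2, byrow = TRUE)
      A <- I2 + dt * Fj
      x <- x + dt * c(phidot, thetadot)
      P <- A %*% P %*% t(A) + Q
    }
    z <- f[k, ]
    if (abs(sqrt(sum(z^2)) - g) > config$obs_gate * g) {
      low_obs[k] <- TRUE
    } else {
      sph <- sin(x[1]); cph <- cos(x[1])
      sth <- sin(x[2]); cth <- cos(x[2])
      h <- g * c(-sth, sph * cth, cph * cth)
      H <- g * matrix(c(
        0,          -cth,
        cph * cth,  -sph * sth,
        -sph * cth, -cph * sth
      ), 3, 2, byrow = TRUE)
      S <- H %*% P %*% t(H) + Rm
      K <- P %*% t(H) %*% solve(S)
      x <- x + as.numeric(K %*% (z - h))
      P <- (I2 - K %*% H) %*% P
    }
    phi[k] <- x[1]
    theta[k] <- x[2]
  }
  list(theta = theta, phi = phi, low_obs = low_obs)
}

#' Attitude time series
#'
#' Bundles per-sample 3-2-1 Euler angles with the corresponding
#' sensor-to-stationary rotation matrices.
#'
#' @param psi,theta,phi Yaw, pitch, roll \[rad\]; `psi` may be a scalar
#'   (recycled, e.g. 0 for the head sensor).
#' @param fs Sampling rate \[Hz\].
#'
#' @return An object of class `attitude_series` with elements `psi`,
#'   `theta`, `phi`, `fs` and the 3 x 3 x n rotation array `T`.
#' @export
attitude_series <- function(psi, theta, phi, fs) {
  n <- length(theta)
  if (length(psi) == 1L) psi <- rep(psi, n)
  if (length(phi) == 1L) phi <- rep(phi, n)
  stopifnot(length(psi) == n, length(phi) == n)
  structure(list(psi = psi, theta = theta, phi = phi, fs = fs,
                 T = euler_to_matrices(psi, theta, phi)),
            class = "attitude_series")
}

#' @export
print.attitude_series <- function(x, ...) {
  cat(sprintf("Attitude series: %d samples at %.6g Hz\n",
              length(x$theta), x$fs))
  invisible(x)
}

#' Integrate the shared vertical yaw rate of the two swing-leg sensors
#'
#' The thigh and lower-leg sensors are assumed to share the same angular
#' velocity about the vertical axis (the leg does not twist appreciably at
#' the knee about z). Their stationary-frame vertical rates are averaged and
#' integrated by the forward Euler method from an initial yaw of zero; both
#' sensors receive the identical yaw series.
#'
#' @param thigh,lower [imu_series()] for the thigh and lower-leg sensors.
#' @param thigh_rp,lower_rp Roll/pitch estimates for the two sensors, as
#'   returned by [estimate_roll_pitch()] (lists with `theta`, `phi`).
#'
#' @return A list with `psi_s1`, `psi_s2` (identical yaw series \[rad\]) and
#'   `omega_z`, the shared stationary-frame vertical rate \[rad/s\].
#' @export
integrate_yaw <- function(thigh, lower, thigh_rp, lower_rp) {
  n <- nrow(thigh$angular_velocity)
  if (nrow(lower$angular_velocity) != n ||
      length(thigh_rp$theta) != n || length(lower_rp$theta) != n) {
    stop("thigh and lower-leg series must have the same length",
         call. = FALSE)
  }
  vertical_rate <- function(imu, rp) {
    w <- imu$angular_velocity
    sth <- sin(rp$theta); cth <- cos(rp$theta)
    sph <- sin(rp$phi); cph <- cos(rp$phi)
    # z row of Ry(theta) Rx(phi); independent of yaw
    -sth * w[, 1] + cth * sph * w[, 2] + cth * cph * w[, 3]
  }
  om1 <- vertical_rate(thigh, thigh_rp)
  om2 <- vertical_rate(lower, lower_rp)
  omega_z <- (om1 + om2) / 2
  dt <- 1 / thigh$fs
  psi <- c(0, cumsum(omega_z[-n]) * dt)
  list(psi_s1 = psi, psi_s2 = psi, omega_z = omega_z)
}

#' Transform IMU accelerations to gravity-free stationary-frame accelerations
#'
#' Rotates each sample's acceleration reading into the stationary frame with
#' the estimated attitude and, for specific-force input, removes gravity:
#' `a = T f - (0, 0, g)`. A stationary sensor then yields `a = 0` at any
#' attitude, and the result is the kinematic acceleration of the sensor
#' (taken as the segment-COM acceleration, the sensors being mounted at the
#' segment COM height).
#'
#' @param imu An [imu_series()].
#' @param att An [attitude_series()] for the same samples.
#' @param g Gravitational acceleration \[m/s^2\].
#' @param input `"specific_force"` (default; gravity is removed) or
#'   `"kinematic"` (reading is already gravity-free in the sensor frame and
#'   is only rotated).
#'
#' @return n x 3 matrix of stationary-frame kinematic accelerations \[m/s^2\].
#' @export
transform_accel <- function(imu, att, g = 9.80665,
                            input = c("specific_force", "kinematic")) {
  input <- match.arg(input)
  n <- nrow(imu$specific_force)
  if (dim(att$T)[3] != n) {
    stop("attitude and IMU series lengths disagree", call. = FALSE)
  }
  a <- rotate_rows(att$T, imu$specific_force)
  if (input == "specific_force") a[, 3] <- a[, 3] - g
  a
}
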