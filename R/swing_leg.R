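# Non-stance (swing) leg subsystem: a two-link chain (thigh; lower leg
# including the foot) suspended from the hip joint Q. From the two sensor
# attitudes the segment COM positions follow by rigid-link geometry; the
# force and moment transmitted to the main system at Q follow by
# Newton-Euler inverse dynamics. Q is treated as a fixed point of the
# hip-anchored translational frame.

#' Swing-leg segment and subsystem COM positions
#'
#' Computes per-sample COM positions of the thigh and lower leg in the
#' hip-anchored frame Q-xyz. Segment COMs sit at height `l` above the distal
#' (bottom) end, i.e. at distance `L - l` below the proximal joint along the
#' segment axis: the thigh COM is `T_s1 (0, 0, -(L_s1 - l_s1))`, the knee is
#' `T_s1 (0, 0, -L_s1)`, and the lower-leg COM hangs `L_s2 - l_s2` below the
#' knee along the lower-leg axis. The subsystem COM is the mass-weighted
#' mean of the two segment COMs.
#'
#' @param att_s1,att_s2 [attitude_series()] of the thigh and lower-leg
#'   sensors (sensor axes aligned with segment axes).
#' @param params [compute_body_params()] output.
#'
#' @return An object of class `subsystem_com_series`: list of n x 3 matrices
#'   `r_s1`, `r_s2`, `r_s` \[m\].
#' @export
segment_coms <- function(att_s1, att_s2, params) {
  n <- dim(att_s1$T)[3]
  if (dim(att_s2$T)[3] != n) {
    stop("thigh and lower-leg attitude series lengths disagree",
         call. = FALSE)
  }
  u_thigh <- c(0, 0, -(params$L_s1 - params$l_s1))
  u_knee <- c(0, 0, -params$L_s1)
  u_shank <- c(0, 0, -(params$L_s2 - params$l_s2))
  one <- matrix(1, n, 1)
  r_s1 <- rotate_rows(att_s1$T, one %*% u_thigh)
  r_s2 <- rotate_rows(att_s1$T, one %*% u_knee) +
    rotate_rows(att_s2$T, one %*% u_shank)
  ms1 <- params$m_s1
  ms2 <- params$m_s2
  r_s <- (ms1 * r_s1 + ms2 * r_s2) / (ms1 + ms2)
  structure(list(r_s1 = r_s1, r_s2 = r_s2, r_s = r_s),
            class = "subsystem_com_series")
}

#' Hip-joint force and moment from swing-leg inverse dynamics
#'
#' Newton-Euler inverse dynamics of the two-link swing leg about the hip
#' joint Q. Per segment, the reaction force is
#' `R_si = -m_si a_si + m_si g_vec` with `g_vec = (0, 0, -g)` and `a_si` the
#' gravity-free stationary-frame COM acceleration; the rotational term is
#' `N_si = T_si (J_si wdot_si + w_si x J_si w_si)` with the gyro rates
#' `w_si` in the sensor frame, their numerical derivative, and the diagonal
#' segment inertia tensor. The wrench transmitted to the main system is
#' `R_s = R_s1 + R_s2` and, from the moment balance of the subsystem about
#' Q, `N_s = -N_s1 - N_s2 + r_s1 x R_s1 + r_s2 x R_s2`. In the static limit
#' `R_s = (0, 0, -(m_s1 + m_s2) g)`: the hanging leg's weight pulls down on
#' the hip.
#'
#' @param att_s1,att_s2 [attitude_series()] of thigh and lower leg.
#' @param acc_s1,acc_s2 n x 3 gravity-free stationary-frame COM
#'   accelerations \[m/s^2\] (from [transform_accel()]).
#' @param gyro_s1,gyro_s2 n x 3 sensor-frame angular velocities \[rad/s\].
#' @param coms [segment_coms()] output.
#' @param params [compute_body_params()] output.
#' @param fs Sampling rate \[Hz\]; the gyro derivative assumes a fixed step.
#' @param gyro_filter Optional [filter_spec()] applied (zero phase) to the
#'   gyro series before differentiation.
#'
#' @return An object of class `hip_load_series`: list with n x 3 matrices
#'   `R_s` \[N\], `N_s` \[N m\] and the per-segment intermediates `R_s1`,
#'   `R_s2`, `N_s1`, `N_s2`.
#' @export
hip_load <- function(att_s1, att_s2, acc_s1, acc_s2, gyro_s1, gyro_s2,
                     coms, params, fs, gyro_filter = NULL) {
  n <- nrow(acc_s1)
  stopifnot(nrow(acc_s2) == n, nrow(gyro_s1) == n, nrow(gyro_s2) == n,
            nrow(coms$r_s1) == n)
  if (!is.null(gyro_filter)) {
    gyro_s1 <- zero_phase_filter(gyro_s1, gyro_filter, fs)
    gyro_s2 <- zero_phase_filter(gyro_s2, gyro_filter, fs)
  }
  g_vec <- c(0, 0, -params$g)
  seg_force <- function(m, acc) {
    -m * acc + matrix(m * g_vec, n, 3, byrow = TRUE)
  }
  seg_moment <- function(Tarr, gyro, J) {
    wd <- differentiate(gyro, fs)
    Jw <- gyro %*% diag(J)
    body <- wd %*% diag(J) + cross_rows(gyro, Jw)
    rotate_rows(Tarr, body)
  }
  R_s1 <- seg_force(params$m_s1, acc_s1)
  R_s2 <- seg_force(params$m_s2, acc_s2)
  N_s1 <- seg_moment(att_s1$T, gyro_s1,
                     c(params$J_s1x, params$J_s1y, params$J_s1z))
  N_s2 <- seg_moment(att_s2$T, gyro_s2,
                     c(params$J_s2x, params$J_s2y, params$J_s2z))
  R_s <- R_s1 + R_s2
  N_s <- -N_s1 - N_s2 + cross_rows(coms$r_s1, R_s1) +
    cross_rows(coms$r_s2, R_s2)
  structure(list(R_s = R_s, N_s = N_s,
                 R_s1 = R_s1, R_s2 = R_s2, N_s1 = N_s1, N_s2 = N_s2),
            class = "hip_load_series")
}
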