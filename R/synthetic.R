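# Forward-kinematic synthetic trial generator. Segment angle trajectories
# are prescribed as sums of sinusoids (optionally ramped in by a smooth
# envelope), so positions, velocities, accelerations, angular velocities and
# angular accelerations all have closed forms. The ground-reaction wrench is
# then computed from the exact nonlinear Newton-Euler balance of the whole
# body, and the three IMU streams are synthesized at the sensor poses. With
# zero noise every emitted signal is analytically consistent with the
# ground-truth kinematics, which is what makes closed-loop pipeline tests
# meaningful.

# ---- angle trajectories -----------------------------------------------------

# One angle = offset + sum of sinusoidal components; components flagged
# `ramped` are multiplied by a smooth half-cosine envelope rising over
# `ramp` seconds (metronome-paced movements start from rest).
angle_traj <- function(offset = 0, amp = numeric(0), freq = numeric(0),
                       phase = 0, ramped = FALSE, ramp = 0) {
  m <- length(amp)
  stopifnot(length(freq) == m)
  if (length(phase) == 1L) phase <- rep(phase, m)
  if (length(ramped) == 1L) ramped <- rep(ramped, m)
  list(offset = offset, amp = amp, freq = freq, phase = phase,
       ramped = ramped, ramp = ramp)
}

eval_envelope <- function(t, ramp) {
  if (ramp <= 0) {
    return(list(e = rep(1, length(t)), de = rep(0, length(t)),
                dde = rep(0, length(t))))
  }
  up <- t < ramp
  x <- pi * t / ramp
  e <- ifelse(up, 0.5 * (1 - cos(x)), 1)
  de <- ifelse(up, 0.5 * (pi / ramp) * sin(x), 0)
  dde <- ifelse(up, 0.5 * (pi / ramp)^2 * cos(x), 0)
  list(e = e, de = de, dde = dde)
}

eval_angle <- function(traj, t) {
  n <- length(t)
  a <- rep(traj$offset, n)
  da <- numeric(n)
  dda <- numeric(n)
  env <- eval_envelope(t, traj$ramp)
  for (i in seq_along(traj$amp)) {
    w <- 2 * pi * traj$freq[i]
    s <- traj$amp[i] * sin(w * t + traj$phase[i])
    ds <- traj$amp[i] * w * cos(w * t + traj$phase[i])
    dds <- -traj$amp[i] * w^2 * sin(w * t + traj$phase[i])
    if (traj$ramped[i]) {
      a <- a + env$e * s
      da <- da + env$de * s + env$e * ds
      dda <- dda + env$dde * s + 2 * env$de * ds + env$e * dds
    } else {
      a <- a + s
      da <- da + ds
      dda <- dda + dds
    }
  }
  list(a = a, da = da, dda = dda)
}

# Orientation, angular velocity and angular acceleration of a segment whose
# 3-2-1 Euler angles follow the given trajectories.
segment_motion <- function(psi_t, theta_t, phi_t, t) {
  psi <- eval_angle(psi_t, t)
  theta <- eval_angle(theta_t, t)
  phi <- eval_angle(phi_t, t)
  n <- length(t)
  R <- euler_to_matrices(psi$a, theta$a, phi$a)
  e3 <- cbind(rep(0, n), 0, 1)
  u_y <- cbind(-sin(psi$a), cos(psi$a), rep(0, n))       # Rz e2
  u_x <- cbind(cos(psi$a) * cos(theta$a),                # Rz Ry e1
               sin(psi$a) * cos(theta$a), -sin(theta$a))
  omega <- psi$da * e3 + theta$da * u_y + phi$da * u_x
  du_y <- cross_rows(psi$da * e3, u_y)
  du_x <- cross_rows(psi$da * e3 + theta$da * u_y, u_x)
  omegadot <- psi$dda * e3 + theta$dda * u_y + theta$da * du_y +
    phi$dda * u_x + phi$da * du_x
  list(R = R, omega = omega, omegadot = omegadot,
       psi = psi$a, theta = theta$a, phi = phi$a)
}

# Kinematics of the point at body-frame offset u from a moving base.
point_on_segment <- function(base, seg, u) {
  n <- nrow(base$pos)
  s <- rotate_rows(seg$R, matrix(u, n, 3, byrow = TRUE))
  vel <- base$vel + cross_rows(seg$omega, s)
  acc <- base$acc + cross_rows(seg$omegadot, s) +
    cross_rows(seg$omega, cross_rows(seg$omega, s))
  list(pos = base$pos + s, vel = vel, acc = acc)
}

static_base <- function(p, n) {
  z <- matrix(0, n, 3)
  list(pos = matrix(p, n, 3, byrow = TRUE), vel = z, acc = z)
}

# World-frame rate of change of a segment's angular momentum about its COM:
# d/dt(R J R' w) = R (J wdot_b + w_b x J w_b).
rotational_term <- function(seg, J) {
  wb <- rotate_rows(seg$R, seg$omega, transpose = TRUE)
  wbd <- rotate_rows(seg$R, seg$omegadot, transpose = TRUE)
  body <- wbd %*% diag(J) + cross_rows(wb, wb %*% diag(J))
  rotate_rows(seg$R, body)
}

# ---- presets ----------------------------------------------------------------

#' Motion preset for a synthetic single-leg-standing trial
#'
#' Defines the prescribed kinematics of one of the three study conditions:
#' `"A_quiet"` (quiet single-leg stance with small postural sway),
#' `"B_updown"` (swing leg oscillating vertically at `swing_freq`),
#' `"C_yaw"` (swing leg rotating back and forth about the vertical axis at
#' `swing_freq`). Sway amplitudes are whole-body COM displacement amplitudes
#' of the sinusoidal components; the corresponding stance-leg/upper-body
#' tilt amplitudes are derived from the subject's segment parameters at
#' generation time and must stay below 5 degrees (linearization regime).
#'
#' @param condition `"A_quiet"`, `"B_updown"` or `"C_yaw"`.
#' @param duration Trial length \[s\].
#' @param fs Sampling rate \[Hz\].
#' @param stance_side `"right"` or `"left"`.
#' @param seed Integer seed fully determining the trial's noise draws.
#' @param ap_amp_mm,ap_freq,ap_phase Anteroposterior COM sway components:
#'   amplitudes \[mm\], frequencies \[Hz\], phases \[rad\].
#' @param ml_amp_mm,ml_freq,ml_phase Mediolateral sway components.
#' @param upper_gain Upper-body tilt relative to stance-leg tilt
#'   (1 = both segments tilt as one).
#' @param thigh_pitch_deg,shank_pitch_deg Baseline pitch of the raised swing
#'   thigh and of the lower leg \[deg\].
#' @param swing_roll_deg Baseline adduction of the swing leg \[deg\]:
#'   positive brings the raised leg towards the body midline (both
#'   segments).
#' @param swing_freq Swing-leg oscillation frequency \[Hz\].
#' @param swing_pitch_amp_deg Length-2 vector: thigh and shank pitch
#'   oscillation amplitudes \[deg\] in condition B.
#' @param yaw_amp_deg Swing-leg yaw oscillation amplitude \[deg\] in
#'   condition C (shared by thigh and lower leg).
#' @param wobble_deg Small incidental swing-leg wobble amplitude \[deg\].
#' @param ramp Envelope rise time \[s\] for the condition B/C oscillations.
#' @param main_pitch_offset_deg,main_roll_offset_deg Constant whole-body
#'   lean \[deg\] (for static fixtures).
#' @param foot_com Optional `(x, y)` \[m\] of the stance-foot COM; by
#'   default it is placed under the baseline-pose COM of the moving
#'   segments, emulating a balanced stance.
#'
#' @return An object of class `motion_preset`.
#' @export
motion_preset <- function(condition = c("A_quiet", "B_updown", "C_yaw"),
                          duration = 45, fs = 100,
                          stance_side = c("right", "left"), seed = 1L,
                          ap_amp_mm = c(6, 2), ap_freq = c(0.3, 0.7),
                          ap_phase = c(0.4, 1.3),
                          ml_amp_mm = c(4, 1.5), ml_freq = c(0.3, 0.7),
                          ml_phase = c(0.9, 2.1),
                          upper_gain = 1.15,
                          thigh_pitch_deg = 30, shank_pitch_deg = 0,
                          swing_roll_deg = 0,
                          swing_freq = 0.75,
                          swing_pitch_amp_deg = c(10, 15),
                          yaw_amp_deg = 15,
                          wobble_deg = 0.5,
                          ramp = 3,
                          main_pitch_offset_deg = 0,
                          main_roll_offset_deg = 0,
                          foot_com = NULL) {
  condition <- match.arg(condition)
  stance_side <- match.arg(stance_side)
  if (duration <= 0 || fs <= 0) {
    stop("'duration' and 'fs' must be positive", call. = FALSE)
  }
  if (length(ap_amp_mm) == 1L) ap_amp_mm <- rep(ap_amp_mm, length(ap_freq))
  if (length(ml_amp_mm) == 1L) ml_amp_mm <- rep(ml_amp_mm, length(ml_freq))
  structure(list(
    condition = condition, duration = duration, fs = fs,
    stance_side = stance_side, seed = as.integer(seed),
    ap_amp = ap_amp_mm / 1000, ap_freq = ap_freq, ap_phase = ap_phase,
    ml_amp = ml_amp_mm / 1000, ml_freq = ml_freq, ml_phase = ml_phase,
    upper_gain = upper_gain,
    # a positive raise angle swings the hanging segment forward (+X),
    # which is a negative 3-2-1 pitch for a downward-pointing segment
    thigh_pitch = -thigh_pitch_deg * pi / 180,
    shank_pitch = -shank_pitch_deg * pi / 180,
    swing_roll = swing_roll_deg * pi / 180,
    swing_freq = swing_freq,
    swing_pitch_amp = swing_pitch_amp_deg * pi / 180,
    yaw_amp = yaw_amp_deg * pi / 180,
    wobble = wobble_deg * pi / 180,
    ramp = ramp,
    main_pitch_offset = main_pitch_offset_deg * pi / 180,
    main_roll_offset = main_roll_offset_deg * pi / 180,
    foot_com = foot_com
  ), class = "motion_preset")
}

#' Measurement noise specification for synthetic trials
#'
#' Defaults are the noise scales used for the pipeline's robustness
#' assessment: accelerometer 0.02 m/s^2, gyroscope 0.2 deg/s, plate force
#' 0.5 N, plate moment 0.1 N m, zero gyro bias.
#'
#' @param accel_sd Accelerometer noise SD \[m/s^2\].
#' @param gyro_sd Gyroscope noise SD \[rad/s\].
#' @param gyro_bias Constant gyro bias magnitude \[rad/s\] (direction drawn
#'   from the trial seed).
#' @param force_sd Plate force noise SD \[N\].
#' @param moment_sd Plate moment noise SD \[N m\].
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(accel_sd = 0.02, gyro_sd = 0.2 * pi / 180,
                       gyro_bias = 0, force_sd = 0.5, moment_sd = 0.1) {
  structure(list(accel_sd = accel_sd, gyro_sd = gyro_sd,
                 gyro_bias = gyro_bias, force_sd = force_sd,
                 moment_sd = moment_sd),
            class = "noise_spec")
}

# Main-system tilt amplitude that yields a given whole-body COM displacement
# amplitude under combined stance-leg (tilt a) and upper-body (tilt k a)
# sway, the swing leg translating with the hip.
tilt_per_com <- function(params, upper_gain) {
  m_main <- params$m_m1 + params$m_m2
  m_sub <- params$m_s1 + params$m_s2
  coef <- (params$m_m1 * params$l_m1 +
             params$m_m2 * (params$L_m1 + upper_gain * params$l_m2) +
             m_sub * params$L_m1) / (m_main + m_sub)
  1 / coef
}

# Build the four segment angle trajectories for a preset.
build_trajectories <- function(preset, params) {
  kt <- tilt_per_com(params, preset$upper_gain)
  leg_pitch_amp <- preset$ap_amp * kt
  leg_roll_amp <- -preset$ml_amp * kt   # +roll tilts towards -Y
  cond <- preset$condition
  wob <- preset$wobble
  swf <- preset$swing_freq

  leg_theta <- angle_traj(preset$main_pitch_offset, leg_pitch_amp,
                          preset$ap_freq, preset$ap_phase)
  leg_phi <- angle_traj(preset$main_roll_offset, leg_roll_amp,
                        preset$ml_freq, preset$ml_phase)
  up_theta <- angle_traj(preset$main_pitch_offset,
                         preset$upper_gain * leg_pitch_amp,
                         preset$ap_freq, preset$ap_phase)
  up_phi <- angle_traj(preset$main_roll_offset,
                       preset$upper_gain * leg_roll_amp,
                       preset$ml_freq, preset$ml_phase)

  thigh_amp <- c(if (cond == "B_updown") preset$swing_pitch_amp[1] else NULL,
                 wob)
  thigh_freq <- c(if (cond == "B_updown") swf else NULL, 0.35)
  thigh_phase <- c(if (cond == "B_updown") 0 else NULL, 0.7)
  thigh_ramped <- c(if (cond == "B_updown") TRUE else NULL, FALSE)
  shank_amp <- c(if (cond == "B_updown") -preset$swing_pitch_amp[2] else NULL,
                 0.6 * wob)
  shank_freq <- c(if (cond == "B_updown") swf else NULL, 0.35)
  shank_phase <- c(if (cond == "B_updown") 0 else NULL, 1.1)
  shank_ramped <- c(if (cond == "B_updown") TRUE else NULL, FALSE)
  yaw_amp <- if (cond == "C_yaw") preset$yaw_amp else numeric(0)
  yaw_freq <- if (cond == "C_yaw") swf else numeric(0)
  # adduction towards the midline: -Y for a right stance leg (swing on the
  # left), +Y for a left stance leg; +roll tilts a hanging segment to +Y
  roll_off <- if (preset$stance_side == "right") -preset$swing_roll else
    preset$swing_roll

  list(
    m1 = list(psi = angle_traj(), theta = leg_theta, phi = leg_phi),
    m2 = list(psi = angle_traj(), theta = up_theta, phi = up_phi),
    s1 = list(
      psi = angle_traj(0, yaw_amp, yaw_freq, 0, TRUE, preset$ramp),
      theta = angle_traj(preset$thigh_pitch, thigh_amp, thigh_freq,
                         thigh_phase, thigh_ramped, preset$ramp),
      phi = angle_traj(roll_off, 0.6 * wob, 0.45, 1.9)
    ),
    s2 = list(
      psi = angle_traj(0, yaw_amp, yaw_freq, 0, TRUE, preset$ramp),
      theta = angle_traj(preset$shank_pitch, shank_amp, shank_freq,
                         shank_phase, shank_ramped, preset$ramp),
      phi = angle_traj(roll_off, 0.4 * wob, 0.45, 2.6)
    ),
    leg_pitch_amp = leg_pitch_amp, leg_roll_amp = leg_roll_amp
  )
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic single-leg-standing trial
#'
#' Evaluates the preset's prescribed segment trajectories analytically,
#' propagates the kinematic chain (stance foot fixed; stance leg about the
#' ankle; upper body about the stance hip P; swing thigh and lower leg
#' suspended from the swing hip Q, with P and Q kept at the same height),
#' computes the exact ground-reaction wrench from the whole-body
#' Newton-Euler balance, and synthesizes the three IMU streams at the
#' segment-COM sensor poses. Gaussian noise and gyro bias are added per
#' `noise`; the trial seed fully determines the random draws.
#'
#' @param preset A [motion_preset()].
#' @param profile A [subject_profile()].
#' @param noise A [noise_spec()], or `NULL` for noiseless output.
#' @param accel_kind `"specific_force"` (accelerometer convention, gravity
#'   included) or `"kinematic"` (gravity-free sensor-frame acceleration);
#'   recorded on the trial so the estimator knows what it is consuming.
#'
#' @return An object of class `synthetic_trial`: `plate`
#'   ([force_plate_series()]), `imu` (list of three [imu_series()]),
#'   `truth` (ground-truth segment kinematics, whole-body COM, hip wrench,
#'   head acceleration, hip positions), plus the preset, profile, derived
#'   parameters and noise specification.
#' @export
generate_trial <- function(preset, profile, noise = NULL,
                           accel_kind = c("specific_force", "kinematic")) {
  accel_kind <- match.arg(accel_kind)
  stopifnot(inherits(preset, "motion_preset"))
  params <- compute_body_params(profile)
  if (preset$stance_side != profile$stance_side) {
    profile$stance_side <- preset$stance_side
    params$stance_side <- preset$stance_side
  }
  n <- round(preset$duration * preset$fs)
  t <- (seq_len(n) - 1) / preset$fs
  traj <- build_trajectories(preset, params)

  max_tilt <- max(abs(traj$m1$theta$offset) + sum(abs(traj$m1$theta$amp)),
                  abs(traj$m1$phi$offset) + sum(abs(traj$m1$phi$amp)),
                  abs(traj$m2$theta$offset) + sum(abs(traj$m2$theta$amp)),
                  abs(traj$m2$phi$offset) + sum(abs(traj$m2$phi$amp)))
  if (max_tilt >= 5 * pi / 180) {
    stop(sprintf(paste0("main-system tilt reaches %.2f deg; presets must ",
                        "stay below 5 deg (small-angle regime)"),
                 max_tilt * 180 / pi), call. = FALSE)
  }

  m1 <- segment_motion(traj$m1$psi, traj$m1$theta, traj$m1$phi, t)
  m2 <- segment_motion(traj$m2$psi, traj$m2$theta, traj$m2$phi, t)
  s1 <- segment_motion(traj$s1$psi, traj$s1$theta, traj$s1$phi, t)
  s2 <- segment_motion(traj$s2$psi, traj$s2$theta, traj$s2$phi, t)

  g <- params$g
  g_vec <- c(0, 0, -g)
  s_w <- if (preset$stance_side == "right") 1 else -1
  ankle <- static_base(c(0, 0, params$L_f), n)
  hipP <- point_on_segment(ankle, m1, c(0, 0, params$L_m1))
  hipQ <- list(pos = hipP$pos +
                 matrix(c(0, s_w * params$w, 0), n, 3, byrow = TRUE),
               vel = hipP$vel, acc = hipP$acc)
  com_m1 <- point_on_segment(ankle, m1, c(0, 0, params$l_m1))
  com_m2 <- point_on_segment(hipP, m2, c(0, 0, params$l_m2))
  head_pt <- point_on_segment(hipP, m2, c(0, 0, params$L_m2))
  com_s1 <- point_on_segment(hipQ, s1, c(0, 0, -(params$L_s1 - params$l_s1)))
  knee <- point_on_segment(hipQ, s1, c(0, 0, -params$L_s1))
  com_s2 <- point_on_segment(knee, s2, c(0, 0, -(params$L_s2 - params$l_s2)))

  segs <- list(
    m1 = list(motion = m1, com = com_m1, m = params$m_m1,
              J = c(params$J_m1x, params$J_m1y,
                    (params$J_m1x + params$J_m1y) / 2)),
    m2 = list(motion = m2, com = com_m2, m = params$m_m2,
              J = c(params$J_m2x, params$J_m2y,
                    (params$J_m2x + params$J_m2y) / 2)),
    s1 = list(motion = s1, com = com_s1, m = params$m_s1,
              J = c(params$J_s1x, params$J_s1y, params$J_s1z)),
    s2 = list(motion = s2, com = com_s2, m = params$m_s2,
              J = c(params$J_s2x, params$J_s2y, params$J_s2z))
  )

  # balanced stance: foot COM defaults under the baseline moving-body COM
  foot_xy <- preset$foot_com
  if (is.null(foot_xy)) {
    base_pose <- baseline_com(preset, params, s_w)
    foot_xy <- base_pose[1:2]
  }
  foot_pos <- c(foot_xy[1], foot_xy[2], params$L_f / 2)

  # exact ground-reaction wrench about the plate origin
  m_moving <- params$m_m1 + params$m_m2 + params$m_s1 + params$m_s2
  F <- matrix(0, n, 3)
  N <- matrix(0, n, 3)
  for (sg in segs) {
    mi <- sg$m
    fi <- mi * (sg$com$acc - matrix(g_vec, n, 3, byrow = TRUE))
    F <- F + fi
    N <- N + rotational_term(sg$motion, sg$J) + cross_rows(sg$com$pos, fi)
  }
  foot_w <- c(0, 0, params$m_f * g)
  F <- F + matrix(foot_w, n, 3, byrow = TRUE)
  N <- N + cross_rows(matrix(foot_pos, n, 3, byrow = TRUE),
                      matrix(foot_w, n, 3, byrow = TRUE))

  # ground-truth whole-body (moving segments) COM and hip wrench
  com_xy <- (params$m_m1 * com_m1$pos + params$m_m2 * com_m2$pos +
               params$m_s1 * com_s1$pos + params$m_s2 * com_s2$pos) / m_moving
  R_s1_true <- -params$m_s1 * com_s1$acc +
    matrix(params$m_s1 * g_vec, n, 3, byrow = TRUE)
  R_s2_true <- -params$m_s2 * com_s2$acc +
    matrix(params$m_s2 * g_vec, n, 3, byrow = TRUE)
  r_s1_true <- com_s1$pos - hipQ$pos
  r_s2_true <- com_s2$pos - hipQ$pos
  N_s_true <- -rotational_term(s1, segs$s1$J) - rotational_term(s2, segs$s2$J) +
    cross_rows(r_s1_true, R_s1_true) + cross_rows(r_s2_true, R_s2_true)

  # sensor streams (sensors at segment COM; head sensor at the head point)
  emit <- function(seg, point) {
    acc_w <- point$acc
    if (accel_kind == "specific_force") {
      acc_w <- acc_w - matrix(g_vec, n, 3, byrow = TRUE)
    }
    list(acc = rotate_rows(seg$R, acc_w, transpose = TRUE),
         gyro = rotate_rows(seg$R, seg$omega, transpose = TRUE))
  }
  raw <- list(head = emit(m2, head_pt), thigh = emit(s1, com_s1),
              lower = emit(s2, com_s2))

  if (!is.null(noise)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(preset$seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    for (nm in names(raw)) {
      raw[[nm]]$acc <- raw[[nm]]$acc +
        matrix(stats::rnorm(3 * n, 0, noise$accel_sd), n, 3)
      bias <- c(0, 0, 0)
      if (noise$gyro_bias > 0) {
        d <- stats::rnorm(3)
        bias <- noise$gyro_bias * d / sqrt(sum(d^2))
      }
      raw[[nm]]$gyro <- raw[[nm]]$gyro +
        matrix(stats::rnorm(3 * n, 0, noise$gyro_sd), n, 3) +
        matrix(bias, n, 3, byrow = TRUE)
    }
    F <- F + matrix(stats::rnorm(3 * n, 0, noise$force_sd), n, 3)
    N <- N + matrix(stats::rnorm(3 * n, 0, noise$moment_sd), n, 3)
  }

  plate <- force_plate_series(t, F, N)
  imu <- list(
    head = imu_series(t, raw$head$acc, raw$head$gyro, "head"),
    thigh = imu_series(t, raw$thigh$acc, raw$thigh$gyro, "thigh"),
    lower_leg = imu_series(t, raw$lower$acc, raw$lower$gyro, "lower_leg")
  )
  truth <- list(
    com = com_series(com_xy[, 1], com_xy[, 2]),
    head_acc = head_pt$acc,
    hip = list(R_s = R_s1_true + R_s2_true, N_s = N_s_true,
               R_s1 = R_s1_true, R_s2 = R_s2_true,
               r_s1 = r_s1_true, r_s2 = r_s2_true),
    hipP = hipP$pos, hipQ = hipQ$pos,
    segments = segs,
    foot_com = foot_pos
  )
  structure(list(time = t, fs = preset$fs, plate = plate, imu = imu,
                 truth = truth, preset = preset, profile = profile,
                 params = params, noise = noise, accel_kind = accel_kind),
            class = "synthetic_trial")
}

# Moving-body COM of the baseline pose (angle offsets only, no oscillation).
baseline_com <- function(preset, params, s_w) {
  p0 <- motion_preset(
    condition = "A_quiet", duration = 2 / preset$fs, fs = preset$fs,
    stance_side = preset$stance_side, seed = preset$seed,
    ap_amp_mm = 0, ap_freq = 1, ap_phase = 0,
    ml_amp_mm = 0, ml_freq = 1, ml_phase = 0,
    upper_gain = preset$upper_gain,
    thigh_pitch_deg = -preset$thigh_pitch * 180 / pi,
    shank_pitch_deg = -preset$shank_pitch * 180 / pi,
    swing_roll_deg = preset$swing_roll * 180 / pi,
    wobble_deg = 0,
    main_pitch_offset_deg = preset$main_pitch_offset * 180 / pi,
    main_roll_offset_deg = preset$main_roll_offset * 180 / pi,
    foot_com = c(0, 0))
  tr <- build_trajectories(p0, params)
  two <- c(0, 1 / preset$fs)
  m1 <- segment_motion(tr$m1$psi, tr$m1$theta, tr$m1$phi, two)
  m2 <- segment_motion(tr$m2$psi, tr$m2$theta, tr$m2$phi, two)
  s1 <- segment_motion(tr$s1$psi, tr$s1$theta, tr$s1$phi, two)
  s2 <- segment_motion(tr$s2$psi, tr$s2$theta, tr$s2$phi, two)
  ankle <- static_base(c(0, 0, params$L_f), 2L)
  hipP <- point_on_segment(ankle, m1, c(0, 0, params$L_m1))
  hipQ <- list(pos = hipP$pos + matrix(c(0, s_w * params$w, 0), 2, 3,
                                       byrow = TRUE),
               vel = hipP$vel, acc = hipP$acc)
  com_m1 <- point_on_segment(ankle, m1, c(0, 0, params$l_m1))
  com_m2 <- point_on_segment(hipP, m2, c(0, 0, params$l_m2))
  com_s1 <- point_on_segment(hipQ, s1, c(0, 0, -(params$L_s1 - params$l_s1)))
  knee <- point_on_segment(hipQ, s1, c(0, 0, -params$L_s1))
  com_s2 <- point_on_segment(knee, s2, c(0, 0, -(params$L_s2 - params$l_s2)))
  m_moving <- params$m_m1 + params$m_m2 + params$m_s1 + params$m_s2
  as.numeric((params$m_m1 * com_m1$pos[1, ] + params$m_m2 * com_m2$pos[1, ] +
                params$m_s1 * com_s1$pos[1, ] +
                params$m_s2 * com_s2$pos[1, ]) / m_moving)
}

#' Ground-truth whole-body COM of a synthetic trial
#'
#' The exact mass-weighted COM of the four moving segments (stance leg,
#' upper body, swing thigh, swing lower leg), in the same plate-origin
#' coordinates as the estimator's output.
#'
#' @param trial A [generate_trial()] result.
#' @return A [com_series()].
#' @export
ground_truth_com <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  trial$truth$com
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial: condition %s, %.0f s at %.6g Hz, stance %s, %s\n",
    x$preset$condition, x$preset$duration, x$fs, x$preset$stance_side,
    if (is.null(x$noise)) "noiseless" else "with sensor noise"))
  invisible(x)
}
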