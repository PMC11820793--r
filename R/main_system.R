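# Main system: the stance leg and upper body as a linearized double-inverted
# pendulum pivoting at the ankle and the stance hip. Per sample, a 3x3
# linear system in (segment COM accelerations, main-system COM displacement)
# couples the plate force balance, the moment balance about the plate
# origin, and the head-acceleration constraint.
#
# Plate convention: the ForcePlateSeries stores the ground-reaction wrench on
# the subject (R_z > 0 upward, moments of the reaction about the plate
# origin). The balance equations are posed in terms of the subject-on-plate
# (action) wrench, so the horizontal force and moment channels are negated
# internally when the right-hand sides are assembled.

#' Force-platform time series
#'
#' @param time Sample times \[s\], uniformly spaced.
#' @param force n x 3 matrix of ground-reaction force on the subject
#'   (R_x, R_y, R_z) \[N\]; R_z > 0 during stance.
#' @param moment n x 3 matrix of the reaction moment about the platform
#'   origin (N_x, N_y, N_z) \[N m\]. Axes: X forward, Y left, Z up.
#'
#' @return An object of class `force_plate_series`.
#' @export
force_plate_series <- function(time, force, moment) {
  force <- unname(as.matrix(force))
  moment <- unname(as.matrix(moment))
  n <- length(time)
  if (nrow(force) != n || nrow(moment) != n ||
      ncol(force) != 3L || ncol(moment) != 3L) {
    stop("'force' and 'moment' must be n x 3 matrices matching 'time'",
         call. = FALSE)
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("sampling is not uniform", call. = FALSE)
  }
  if (any(force[, 3] <= 0)) {
    warning("vertical reaction R_z is not positive everywhere; ",
            "check the plate sign convention", call. = FALSE)
  }
  structure(list(time = as.numeric(time), fs = 1 / dt[1],
                 force = force, moment = moment),
            class = "force_plate_series")
}

#' @export
print.force_plate_series <- function(x, ...) {
  cat(sprintf("Force-plate series: %d samples at %.6g Hz, median R_z %.1f N\n",
              length(x$time), x$fs, stats::median(x$force[, 3])))
  invisible(x)
}

# Assemble and solve the per-sample 3x3 systems shared by both planes.
# rows: (i) force balance, (ii) moment balance about the plate origin,
# (iii) head-acceleration constraint. Only the moment row's third
# coefficient (c23) varies with time, through the vertical hip load.
solve_plane <- function(c21, c22, c23, b1, b2, b3, params,
                        cond_threshold = 1e10) {
  n <- length(b1)
  m1 <- params$m_m1; m2 <- params$m_m2
  h1 <- params$L_m1 * (params$l_m2 - params$L_m2) /
    (params$l_m1 * params$l_m2)
  h2 <- params$L_m2 / params$l_m2
  acc1 <- numeric(n); acc2 <- numeric(n); com <- numeric(n)
  resid <- numeric(n)
  flagged <- logical(n)
  prev <- c(0, 0, 0)
  have_prev <- FALSE
  for (k in seq_len(n)) {
    A <- matrix(c(m1, m2, 0,
                  c21, c22, c23[k],
                  h1, h2, 0), 3, 3, byrow = TRUE)
    b <- c(b1[k], b2[k], b3[k])
    if (rcond(A) < 1 / cond_threshold) {
      flagged[k] <- TRUE
      if (!have_prev) {
        stop("main-system matrix is singular from the first sample",
             call. = FALSE)
      }
      sol <- prev
    } else {
      sol <- solve(A, b)
      prev <- sol
      have_prev <- TRUE
    }
    acc1[k] <- sol[1]; acc2[k] <- sol[2]; com[k] <- sol[3]
    bn <- sqrt(sum(b^2))
    resid[k] <- sqrt(sum((A %*% sol - b)^2)) / max(bn, .Machine$double.eps)
  }
  if (all(flagged)) stop("all samples singular", call. = FALSE)
  list(acc1 = acc1, acc2 = acc2, com = com, residual = resid,
       flagged = flagged)
}

#' Solve the sagittal-plane main-system equations
#'
#' Per sample, solves the 3x3 linear system in the stance-leg COM
#' acceleration, upper-body COM acceleration and main-system COM
#' displacement `X_m`: (i) the horizontal force balance with the plate and
#' hip forces, (ii) the moment balance about the plate origin with
#' coefficients
#' `A21 = -J_m1y/l_m1 - m_m1 (L_f + l_m1) + J_m2y L_m1/(l_m1 l_m2)`,
#' `A22 = -J_m2y/l_m2 - m_m2 (L_f + L_m1 + l_m2)`,
#' `A23 = ((m_m1 + m_m2) g - R_sz) L_m1/l_m`,
#' and (iii) the head-acceleration constraint. The hip displacement is
#' approximated through the COM displacement by `(L_m1/l_m) X_m`, which is
#' exact when the two segments tilt as one.
#'
#' @param plate A [force_plate_series()] with the horizontal forces already
#'   drift-filtered.
#' @param hip A [hip_load_series()].
#' @param head_acc_x Stationary-frame horizontal (X) head acceleration
#'   \[m/s^2\].
#' @param params [compute_body_params()] output.
#' @param cond_threshold Samples whose 3x3 matrix has condition number above
#'   this are flagged and held at the previous valid solution.
#'
#' @return A list with per-sample `acc_m1`, `acc_m2` \[m/s^2\], `X_m` \[m\],
#'   the coefficient records `A21`, `A22`, `A23`, relative back-substitution
#'   residuals and a logical `flagged` vector.
#' @export
solve_sagittal <- function(plate, hip, head_acc_x, params,
                           cond_threshold = 1e10) {
  n <- length(head_acc_x)
  stopifnot(nrow(plate$force) == n, nrow(hip$R_s) == n)
  g <- params$g
  arm <- params$L_f + params$L_m1
  A21 <- -params$J_m1y / params$l_m1 - params$m_m1 * (params$L_f + params$l_m1) +
    params$J_m2y * params$L_m1 / (params$l_m1 * params$l_m2)
  A22 <- -params$J_m2y / params$l_m2 -
    params$m_m2 * (params$L_f + params$L_m1 + params$l_m2)
  A23 <- ((params$m_m1 + params$m_m2) * g - hip$R_s[, 3]) *
    params$L_m1 / params$l_m
  # stored reaction -> action: R_x_action = -force[,1], N_y_action = -moment[,2]
  b1 <- plate$force[, 1] + hip$R_s[, 1]
  b2 <- -plate$moment[, 2] - hip$N_s[, 2] - hip$R_s[, 1] * arm
  sol <- solve_plane(A21, A22, A23, b1, b2, head_acc_x, params,
                     cond_threshold)
  list(acc_m1 = sol$acc1, acc_m2 = sol$acc2, X_m = sol$com,
       A21 = A21, A22 = A22, A23 = A23,
       residual = sol$residual, flagged = sol$flagged)
}

#' Solve the frontal-plane main-system equations
#'
#' Mirror of [solve_sagittal()] for mediolateral motion, with coefficients
#' `B21 = +J_m1x/l_m1 + m_m1 (L_f + l_m1) - J_m2x L_m1/(l_m1 l_m2)`,
#' `B22 = +J_m2x/l_m2 + m_m2 (L_f + L_m1 + l_m2)`,
#' `B23 = (-(m_m1 + m_m2) g + R_sz) L_m1/l_m`.
#' The moment row additionally carries the vertical hip load acting at the
#' lateral inter-hip offset `w`; that term enters with a positive sign when
#' the stance leg is the left one.
#'
#' @inheritParams solve_sagittal
#' @param head_acc_y Stationary-frame lateral (Y) head acceleration
#'   \[m/s^2\].
#' @param stance_side `"right"` or `"left"`.
#'
#' @return As [solve_sagittal()], with `Y_m` and coefficients `B21`, `B22`,
#'   `B23`.
#' @export
solve_frontal <- function(plate, hip, head_acc_y, params,
                          stance_side = c("right", "left"),
                          cond_threshold = 1e10) {
  stance_side <- match.arg(stance_side)
  n <- length(head_acc_y)
  stopifnot(nrow(plate$force) == n, nrow(hip$R_s) == n)
  g <- params$g
  arm <- params$L_f + params$L_m1
  B21 <- params$J_m1x / params$l_m1 + params$m_m1 * (params$L_f + params$l_m1) -
    params$J_m2x * params$L_m1 / (params$l_m1 * params$l_m2)
  B22 <- params$J_m2x / params$l_m2 +
    params$m_m2 * (params$L_f + params$L_m1 + params$l_m2)
  B23 <- (-(params$m_m1 + params$m_m2) * g + hip$R_s[, 3]) *
    params$L_m1 / params$l_m
  s_w <- if (stance_side == "left") 1 else -1
  b1 <- plate$force[, 2] + hip$R_s[, 2]
  b2 <- -plate$moment[, 1] - hip$N_s[, 1] + hip$R_s[, 2] * arm +
    s_w * hip$R_s[, 3] * params$w
  sol <- solve_plane(B21, B22, B23, b1, b2, head_acc_y, params,
                     cond_threshold)
  list(acc_m1 = sol$acc1, acc_m2 = sol$acc2, Y_m = sol$com,
       B21 = B21, B22 = B22, B23 = B23,
       residual = sol$residual, flagged = sol$flagged)
}

#' Linearization residual of the main-system moment balance
#'
#' Diagnostic for the linearized double-inverted-pendulum model: evaluates,
#' on a synthetic trial's ground truth, the moment balance about the plate
#' origin with gravity and the hip-wrench transport kept exact and only the
#' pendulum inertia terms linearized. The residual isolates what the
#' linearization discards: with sway about a small constant lean it is
#' dominated by the vertical-acceleration transport term and grows
#' quadratically with sway amplitude (symmetric sway about the vertical has
#' a vanishing quadratic term because the sine expansion is odd, leaving
#' only the cubic).
#'
#' @param trial A [generate_trial()] result (noise-free inputs give the
#'   cleanest diagnostic).
#' @param plane `"sagittal"` or `"frontal"`.
#'
#' @return Numeric residual series \[N m\].
#' @export
linearization_residual <- function(trial,
                                   plane = c("sagittal", "frontal")) {
  plane <- match.arg(plane)
  stopifnot(inherits(trial, "synthetic_trial"))
  pa <- trial$params
  m1 <- trial$truth$segments$m1$com
  m2 <- trial$truth$segments$m2$com
  hip <- trial$truth$hip
  m12 <- pa$m_m1 + pa$m_m2
  if (plane == "sagittal") {
    Xm <- (pa$m_m1 * m1$pos[, 1] + pa$m_m2 * m2$pos[, 1]) / m12
    A21 <- -pa$J_m1y / pa$l_m1 - pa$m_m1 * (pa$L_f + pa$l_m1) +
      pa$J_m2y * pa$L_m1 / (pa$l_m1 * pa$l_m2)
    A22 <- -pa$J_m2y / pa$l_m2 -
      pa$m_m2 * (pa$L_f + pa$L_m1 + pa$l_m2)
    lhs <- A21 * m1$acc[, 1] + A22 * m2$acc[, 1] + m12 * pa$g * Xm -
      hip$R_s[, 3] * trial$truth$hipQ[, 1]
    rhs <- -trial$plate$moment[, 2] - hip$N_s[, 2] -
      hip$R_s[, 1] * trial$truth$hipQ[, 3]
  } else {
    Ym <- (pa$m_m1 * m1$pos[, 2] + pa$m_m2 * m2$pos[, 2]) / m12
    B21 <- pa$J_m1x / pa$l_m1 + pa$m_m1 * (pa$L_f + pa$l_m1) -
      pa$J_m2x * pa$L_m1 / (pa$l_m1 * pa$l_m2)
    B22 <- pa$J_m2x / pa$l_m2 +
      pa$m_m2 * (pa$L_f + pa$L_m1 + pa$l_m2)
    lhs <- B21 * m1$acc[, 2] + B22 * m2$acc[, 2] - m12 * pa$g * Ym +
      hip$R_s[, 3] * trial$truth$hipQ[, 2]
    rhs <- -trial$plate$moment[, 1] - hip$N_s[, 1] +
      hip$R_s[, 2] * trial$truth$hipQ[, 3]
  }
  lhs - rhs
}

#' Solve both planes of the main system
#'
#' Convenience wrapper running [solve_sagittal()] and [solve_frontal()] on
#' the same inputs.
#'
#' @inheritParams solve_sagittal
#' @param head_acc n x 3 stationary-frame head acceleration \[m/s^2\].
#' @param stance_side `"right"` or `"left"`.
#'
#' @return An object of class `main_com_solution` with fields `X_m`, `Y_m`,
#'   the per-plane accelerations, coefficient records, residuals and flags.
#' @export
solve_main <- function(plate, hip, head_acc, params,
                       stance_side = c("right", "left"),
                       cond_threshold = 1e10) {
  stance_side <- match.arg(stance_side)
  sag <- solve_sagittal(plate, hip, head_acc[, 1], params, cond_threshold)
  fro <- solve_frontal(plate, hip, head_acc[, 2], params, stance_side,
                       cond_threshold)
  structure(list(X_m = sag$X_m, Y_m = fro$Y_m, sagittal = sag,
                 frontal = fro, stance_side = stance_side),
            class = "main_com_solution")
}
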