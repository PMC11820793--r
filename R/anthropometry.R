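# Segment inertial parameters of the rigid-link models, scaled from subject
# height H [m] and mass M [kg]. Masses scale with M, lengths with H and
# moments of inertia with M*H^2; the five segment mass fractions sum to 1.

#' Subject profile
#'
#' Minimal anthropometric description of a subject: standing height, body
#' mass and which leg carries the body during the trial.
#'
#' @param height Standing height in metres.
#' @param mass Body mass in kilograms.
#' @param stance_side `"right"` or `"left"`; side of the stance (support) leg.
#'
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile(1.73, 60.6)
#' @export
subject_profile <- function(height, mass, stance_side = c("right", "left")) {
  stance_side <- match.arg(stance_side)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0) {
    stop("'height' must be a single positive number [m]", call. = FALSE)
  }
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) ||
      mass <= 0) {
    stop("'mass' must be a single positive number [kg]", call. = FALSE)
  }
  structure(
    list(height = height, mass = mass, stance_side = stance_side),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject: H = %.3f m, M = %.1f kg, stance side = %s\n",
              x$height, x$mass, x$stance_side))
  invisible(x)
}

# Scaling coefficients of the five-segment model. Segment subscripts:
# m2 upper body, m1 stance leg, f stance foot, s1 non-stance thigh,
# s2 non-stance lower leg + foot. l is the COM height measured from the
# distal (bottom) end of the segment.
.seg_coef <- list(
  mass = c(m2 = 0.656, m1 = 0.161, f = 0.011, s1 = 0.110, s2 = 0.062),
  # moments of inertia about the segment COM, coefficient of M*H^2
  J = c(m2x = 1.30e-2, m2y = 1.10e-2,
        m1x = 2.53e-3, m1y = 2.56e-3,
        s1x = 4.81e-4, s1y = 5.10e-4, s1z = 1.53e-4,
        s2x = 4.86e-4, s2y = 4.92e-4, s2z = 2.89e-4),
  # COM heights l and segment lengths L, coefficient of H
  l = c(m2 = 0.169, m1 = 0.302, s1 = 0.129, s2 = 0.155),
  L = c(m2 = 0.406, m1 = 0.491, s1 = 0.245, s2 = 0.285),
  L_f = 0.039,   # ankle-joint height
  l_m = 0.589,   # whole-body COM height
  w   = 0.100    # inter-hip distance
)

#' Compute body-segment parameters from a subject profile
#'
#' Evaluates all segment masses, lengths, COM heights and moments of inertia
#' of the five-segment model (upper body, stance leg, stance foot, non-stance
#' thigh, non-stance lower leg including the foot) as linear functions of
#' body mass `M` and height `H`: masses as fractions of `M`, lengths and COM
#' heights as fractions of `H`, and COM moments of inertia as multiples of
#' `M * H^2`. The five mass fractions sum to one, so the segment masses
#' conserve total body mass.
#'
#' @param profile A [subject_profile()].
#' @param g Gravitational acceleration in m/s^2.
#'
#' @return An object of class `body_params`: a list with segment masses
#'   (`m_m2`, `m_m1`, `m_f`, `m_s1`, `m_s2` \[kg\]), lengths `L_*` and COM
#'   heights `l_*` \[m\], COM moments of inertia `J_*` \[kg m^2\], ankle
#'   height `L_f`, whole-body COM height `l_m`, inter-hip distance `w`, and
#'   `g`.
#' @examples
#' p <- compute_body_params(subject_profile(1.70, 62))
#' p$m_m2  # 0.656 * 62
#' @export
compute_body_params <- function(profile, g = 9.80665) {
  if (!inherits(profile, "subject_profile")) {
    profile <- do.call(subject_profile, as.list(profile))
  }
  H <- profile$height
  M <- profile$mass
  cf <- .seg_coef
  MH2 <- M * H^2
  out <- list(
    m_m2 = cf$mass[["m2"]] * M,
    J_m2x = cf$J[["m2x"]] * MH2, J_m2y = cf$J[["m2y"]] * MH2,
    l_m2 = cf$l[["m2"]] * H, L_m2 = cf$L[["m2"]] * H,
    m_m1 = cf$mass[["m1"]] * M,
    J_m1x = cf$J[["m1x"]] * MH2, J_m1y = cf$J[["m1y"]] * MH2,
    l_m1 = cf$l[["m1"]] * H, L_m1 = cf$L[["m1"]] * H,
    m_f = cf$mass[["f"]] * M,
    L_f = cf$L_f * H,
    m_s1 = cf$mass[["s1"]] * M,
    J_s1x = cf$J[["s1x"]] * MH2, J_s1y = cf$J[["s1y"]] * MH2,
    J_s1z = cf$J[["s1z"]] * MH2,
    l_s1 = cf$l[["s1"]] * H, L_s1 = cf$L[["s1"]] * H,
    m_s2 = cf$mass[["s2"]] * M,
    J_s2x = cf$J[["s2x"]] * MH2, J_s2y = cf$J[["s2y"]] * MH2,
    J_s2z = cf$J[["s2z"]] * MH2,
    l_s2 = cf$l[["s2"]] * H, L_s2 = cf$L[["s2"]] * H,
    l_m = cf$l_m * H,
    w = cf$w * H,
    g = g,
    height = H,
    mass = M,
    stance_side = profile$stance_side
  )
  class(out) <- "body_params"
  out
}

#' @export
print.body_params <- function(x, ...) {
  cat(sprintf("Body parameters (H = %.3f m, M = %.1f kg):\n", x$height, x$mass))
  cat(sprintf("  upper body  m = %6.3f kg, l = %.3f m, L = %.3f m\n",
              x$m_m2, x$l_m2, x$L_m2))
  cat(sprintf("  stance leg  m = %6.3f kg, l = %.3f m, L = %.3f m\n",
              x$m_m1, x$l_m1, x$L_m1))
  cat(sprintf("  stance foot m = %6.3f kg, ankle height = %.3f m\n",
              x$m_f, x$L_f))
  cat(sprintf("  swing thigh m = %6.3f kg, l = %.3f m, L = %.3f m\n",
              x$m_s1, x$l_s1, x$L_s1))
  cat(sprintf("  swing shank m = %6.3f kg, l = %.3f m, L = %.3f m\n",
              x$m_s2, x$l_s2, x$L_s2))
  cat(sprintf("  whole body  l_m = %.3f m, w = %.3f m, g = %.5f m/s^2\n",
              x$l_m, x$w, x$g))
  invisible(x)
}
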