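# Whole-body COM fusion, centre of pressure, and validation metrics.

#' Fuse main-system and subsystem COM displacements
#'
#' Mass-weighted combination of the main-system COM (stance leg + upper
#' body) and the swing-leg subsystem COM into the whole-body COM:
#' `X_b = ((m_m1 + m_m2) X_m + (m_s1 + m_s2) x_s) / M_eff` and
#' `Y_b = ((m_m1 + m_m2) Y_m + (m_s1 + m_s2)(y_s + s w)) / M_eff`, with
#' `M_eff = m_m1 + m_m2 + m_s1 + m_s2` (the static stance foot is not part
#' of the moving body) and `s = +1` when the stance leg is the right one:
#' the swing hip sits at the lateral offset `w` on the swing side. The
#' horizontal displacement of the hip joint is ignored in the fusion.
#'
#' @param main A `main_com_solution` from [solve_main()], or a list with
#'   numeric `X_m`, `Y_m` \[m\].
#' @param sub A [segment_coms()] result.
#' @param params [compute_body_params()] output.
#' @param stance_side `"right"` or `"left"`.
#'
#' @return An object of class `com_series`: list with `X_b`, `Y_b` \[m\].
#' @export
combine_com <- function(main, sub, params, stance_side = c("right", "left")) {
  if (missing(stance_side) && !is.null(main$stance_side)) {
    stance_side <- main$stance_side
  }
  stance_side <- match.arg(stance_side)
  m_main <- params$m_m1 + params$m_m2
  m_sub <- params$m_s1 + params$m_s2
  m_eff <- m_main + m_sub
  s_w <- if (stance_side == "right") 1 else -1
  X_b <- (m_main * main$X_m + m_sub * sub$r_s[, 1]) / m_eff
  Y_b <- (m_main * main$Y_m + m_sub * (sub$r_s[, 2] + s_w * params$w)) / m_eff
  com_series(X_b, Y_b)
}

#' Whole-body COM series
#'
#' @param X_b,Y_b Anteroposterior and mediolateral COM displacement \[m\].
#' @return An object of class `com_series`.
#' @export
com_series <- function(X_b, Y_b) {
  stopifnot(length(X_b) == length(Y_b))
  structure(list(X_b = as.numeric(X_b), Y_b = as.numeric(Y_b)),
            class = "com_series")
}

#' @export
print.com_series <- function(x, ...) {
  cat(sprintf("COM series: %d samples, sd AP %.2f mm, sd ML %.2f mm\n",
              length(x$X_b), 1000 * stats::sd(x$X_b), 1000 * stats::sd(x$Y_b)))
  invisible(x)
}

#' Centre of pressure from the force-plate wrench
#'
#' `COP_X = (-N_y - R_x h) / R_z` and `COP_Y = (N_x - R_y h) / R_z`, with
#' the stored ground-reaction wrench and the depth `h` of the plate's sensor
#' plane below its surface. Samples whose vertical load is below `fz_min`
#' are masked as `NA`.
#'
#' @param plate A [force_plate_series()].
#' @param h Sensor-plane depth \[m\].
#' @param fz_min Minimum vertical load \[N\] for a defined COP.
#'
#' @return List with `COP_X`, `COP_Y` \[m\] (class `cop_series`).
#' @export
compute_cop <- function(plate, h = 0, fz_min = 50) {
  Rz <- plate$force[, 3]
  ok <- Rz >= fz_min
  COP_X <- ifelse(ok, (-plate$moment[, 2] - plate$force[, 1] * h) / Rz, NA_real_)
  COP_Y <- ifelse(ok, (plate$moment[, 1] - plate$force[, 2] * h) / Rz, NA_real_)
  structure(list(COP_X = COP_X, COP_Y = COP_Y), class = "cop_series")
}

#' Agreement metrics between an estimated and a reference series
#'
#' Pearson's correlation coefficient and the root-mean-square error over an
#' evaluation window (by default samples 1001 to 4000, i.e. 10 s to 40 s of
#' a trial sampled at 100 Hz, keeping filter edges out of the score). Also
#' reported: the RMS amplitude of the mean-removed reference and the ratio
#' RMSE/RMS, a scale-free accuracy measure.
#'
#' @param estimate,reference Numeric series of equal length \[m or any
#'   common unit\].
#' @param window Integer indices of the evaluation window.
#'
#' @return An object of class `metrics_report`: list with `r`, `rmse`,
#'   `rms_ref`, `rmse_rms_ratio` and `window` (in the units of the inputs).
#'   With a constant reference `r` is undefined and returned as `NA` with a
#'   warning; the RMSE is still computed.
#' @export
com_metrics <- function(estimate, reference, window = 1001:4000) {
  n <- length(estimate)
  if (length(reference) != n) {
    stop("estimate and reference lengths differ", call. = FALSE)
  }
  if (min(window) < 1L || max(window) > n) {
    stop(sprintf("evaluation window [%d, %d] outside data (n = %d)",
                 min(window), max(window), n), call. = FALSE)
  }
  qe <- estimate[window]
  qt <- reference[window]
  rmse <- sqrt(mean((qe - qt)^2))
  rms_ref <- sqrt(mean((qt - mean(qt))^2))
  if (rms_ref == 0 || stats::sd(qe) == 0) {
    warning("constant series in window: correlation undefined",
            call. = FALSE)
    r <- NA_real_
  } else {
    r <- sum((qe - mean(qe)) * (qt - mean(qt))) /
      sqrt(sum((qe - mean(qe))^2) * sum((qt - mean(qt))^2))
  }
  structure(list(r = r, rmse = rmse, rms_ref = rms_ref,
                 rmse_rms_ratio = if (rms_ref > 0) rmse / rms_ref else NA_real_,
                 window = range(window)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "r = %.4f, RMSE = %.4g, RMS(ref) = %.4g, RMSE/RMS = %.3f (samples %d-%d)\n",
    x$r, x$rmse, x$rms_ref, x$rmse_rms_ratio, x$window[1], x$window[2]))
  invisible(x)
}
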