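# CSV formats, run configuration, and the file-level entry points used by
# the command-line script. All files are SI-unit CSVs; millimetres appear
# only in the COM/COP output columns (the reporting convention of the
# field).

#' Write / read an IMU CSV
#'
#' Columns `time_s, ax, ay, az, gx, gy, gz` (m/s^2 and rad/s, sensor frame).
#'
#' @param imu An [imu_series()].
#' @param path File path.
#' @return `read_imu_csv` returns an [imu_series()].
#' @export
write_imu_csv <- function(imu, path) {
  df <- data.frame(time_s = imu$time,
                   ax = imu$specific_force[, 1],
                   ay = imu$specific_force[, 2],
                   az = imu$specific_force[, 3],
                   gx = imu$angular_velocity[, 1],
                   gy = imu$angular_velocity[, 2],
                   gz = imu$angular_velocity[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param placement Sensor placement of the file being read.
#' @export
read_imu_csv <- function(path, placement = c("head", "thigh", "lower_leg")) {
  placement <- match.arg(placement)
  df <- utils::read.csv(path)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' lacks required columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  imu_series(df$time_s, as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]), placement)
}

#' Write / read a force-plate CSV
#'
#' Columns `time_s, Fx, Fy, Fz, Mx, My, Mz`: ground-reaction force \[N\] and
#' reaction moment about the platform origin \[N m\], axes X forward, Y
#' left, Z up.
#'
#' @param plate A [force_plate_series()].
#' @param path File path.
#' @return `read_plate_csv` returns a [force_plate_series()].
#' @export
write_plate_csv <- function(plate, path) {
  df <- data.frame(time_s = plate$time,
                   Fx = plate$force[, 1], Fy = plate$force[, 2],
                   Fz = plate$force[, 3],
                   Mx = plate$moment[, 1], My = plate$moment[, 2],
                   Mz = plate$moment[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "Fx", "Fy", "Fz", "Mx", "My", "Mz")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' lacks required columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  force_plate_series(df$time_s, as.matrix(df[, c("Fx", "Fy", "Fz")]),
                     as.matrix(df[, c("Mx", "My", "Mz")]))
}

#' Write / read a COM (and optionally COP) CSV
#'
#' Columns `time_s, COM_X_mm, COM_Y_mm` and, when a COP is supplied,
#' `COP_X_mm, COP_Y_mm`.
#'
#' @param com A [com_series()] (metres; written in millimetres).
#' @param time Sample times \[s\].
#' @param path File path.
#' @param cop Optional `cop_series`.
#' @return `read_com_csv` returns a list with `time` and [com_series()]
#'   `com` (metres).
#' @export
write_com_csv <- function(com, time, path, cop = NULL) {
  df <- data.frame(time_s = time,
                   COM_X_mm = 1000 * com$X_b, COM_Y_mm = 1000 * com$Y_b)
  if (!is.null(cop)) {
    df$COP_X_mm <- 1000 * cop$COP_X
    df$COP_Y_mm <- 1000 * cop$COP_Y
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_com_csv
#' @export
read_com_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "COM_X_mm", "COM_Y_mm")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' lacks required columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  list(time = df$time_s,
       com = com_series(df$COM_X_mm / 1000, df$COM_Y_mm / 1000))
}

#' Write a synthetic trial as a CSV bundle
#'
#' Writes `plate.csv`, `imu_head.csv`, `imu_thigh.csv`,
#' `imu_lower_leg.csv`, `ground_truth_com.csv` and a `manifest.json`
#' recording the preset, seed and noise specification.
#'
#' @param trial A [generate_trial()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_plate_csv(trial$plate, file.path(dir, "plate.csv"))
  write_imu_csv(trial$imu$head, file.path(dir, "imu_head.csv"))
  write_imu_csv(trial$imu$thigh, file.path(dir, "imu_thigh.csv"))
  write_imu_csv(trial$imu$lower_leg, file.path(dir, "imu_lower_leg.csv"))
  write_com_csv(trial$truth$com, trial$time,
                file.path(dir, "ground_truth_com.csv"))
  manifest <- list(
    condition = trial$preset$condition,
    seed = trial$preset$seed,
    duration_s = trial$preset$duration,
    fs_hz = trial$fs,
    stance_side = trial$preset$stance_side,
    accel_kind = trial$accel_kind,
    subject = list(height_m = trial$profile$height,
                   mass_kg = trial$profile$mass),
    noise = if (is.null(trial$noise)) NULL else unclass(trial$noise),
    files = c("plate.csv", "imu_head.csv", "imu_thigh.csv",
              "imu_lower_leg.csv", "ground_truth_com.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a flat key-value run configuration
#'
#' The run configuration is a plain text file of `key = value` lines
#' (`#` comments allowed). Values are parsed as numbers where possible,
#' `true`/`false` as logicals, everything else as strings.
#'
#' @param path File path.
#' @return `read_run_config` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else val
  }
  out
}

#' @rdname read_run_config
#' @param config Named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' Default run configuration
#'
#' All keys understood by [run_estimate()], with their defaults. File-path
#' keys are empty and must be filled in.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(
    subject_height = 1.73, subject_mass = 60.6, stance_side = "right",
    plate_csv = "", imu_head_csv = "", imu_thigh_csv = "",
    imu_lower_leg_csv = "", reference_csv = "", out_dir = ".",
    accel_input = "specific_force",
    hp_cutoff = 0.1, hp_order = 4, lp_cutoff = 3, lp_order = 4,
    ekf_gyro_noise = 0.005, ekf_accel_noise = 0.05,
    ekf_accel_dynamic_sd = 3.0, ekf_init_cov = 0.1, ekf_obs_gate = 0.5,
    window_start = 1001, window_end = 4000,
    cond_threshold = 1e10, cop_h = 0, cop_fz_min = 50,
    g = 9.80665, debug = FALSE
  )
}

config_to_estimator <- function(cfg) {
  estimator_config(
    g = cfg$g,
    ekf = ekf_config(cfg$ekf_gyro_noise, cfg$ekf_accel_noise,
                     cfg$ekf_accel_dynamic_sd, cfg$ekf_init_cov,
                     cfg$ekf_obs_gate),
    hp = filter_spec("highpass", cfg$hp_cutoff, cfg$hp_order),
    lp = filter_spec("lowpass", cfg$lp_cutoff, cfg$lp_order),
    window = c(cfg$window_start, cfg$window_end),
    cond_threshold = cfg$cond_threshold,
    accel_input = cfg$accel_input,
    cop_h = cfg$cop_h, cop_fz_min = cfg$cop_fz_min
  )
}

#' Run the estimation pipeline from a configuration
#'
#' Reads the plate, IMU and optional reference CSVs named in the
#' configuration, runs [estimate_com()], writes `com_cop.csv` (smoothed COM
#' and COP, mm) and `com_cop_centered.csv` (mean-removed over the
#' evaluation window, the displacement convention used for sway plots) to
#' the output directory, plus `metrics.json` when a reference is given and
#' `debug.csv` with intermediate series when `debug` is set.
#'
#' @param config Named list, see [default_run_config()]; missing keys take
#'   their defaults.
#' @return The `com_estimate`, invisibly, with a `metrics` element when a
#'   reference was supplied.
#' @export
run_estimate <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  for (key in c("plate_csv", "imu_head_csv", "imu_thigh_csv",
                "imu_lower_leg_csv")) {
    if (!nzchar(cfg[[key]])) {
      stop(sprintf("config key '%s' is required", key), call. = FALSE)
    }
    if (!file.exists(cfg[[key]])) {
      stop(sprintf("file not found: %s (%s)", cfg[[key]], key),
           call. = FALSE)
    }
  }
  profile <- subject_profile(cfg$subject_height, cfg$subject_mass,
                             cfg$stance_side)
  plate <- read_plate_csv(cfg$plate_csv)
  est <- estimate_com(plate,
                      read_imu_csv(cfg$imu_head_csv, "head"),
                      read_imu_csv(cfg$imu_thigh_csv, "thigh"),
                      read_imu_csv(cfg$imu_lower_leg_csv, "lower_leg"),
                      profile, config_to_estimator(cfg))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_com_csv(est$com, est$time, file.path(cfg$out_dir, "com_cop.csv"),
                cop = est$cop)
  win <- seq(min(cfg$window_start, length(est$time)),
             min(cfg$window_end, length(est$time)))
  centered <- com_series(est$com$X_b - mean(est$com$X_b[win]),
                         est$com$Y_b - mean(est$com$Y_b[win]))
  ccop <- est$cop
  if (!anyNA(ccop$COP_X)) {
    ccop$COP_X <- ccop$COP_X - mean(ccop$COP_X[win])
    ccop$COP_Y <- ccop$COP_Y - mean(ccop$COP_Y[win])
  }
  write_com_csv(centered, est$time,
                file.path(cfg$out_dir, "com_cop_centered.csv"), cop = ccop)
  if (nzchar(cfg$reference_csv)) {
    ref <- read_com_csv(cfg$reference_csv)
    metrics <- validate_estimate(est, ref$com,
                                 seq(cfg$window_start, cfg$window_end))
    rep <- lapply(metrics, function(m) list(
      r = m$r, rmse_mm = 1000 * m$rmse, rms_ref_mm = 1000 * m$rms_ref,
      rmse_rms_ratio = m$rmse_rms_ratio,
      window = as.integer(m$window)))
    jsonlite::write_json(rep, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    est$metrics <- metrics
  }
  if (isTRUE(cfg$debug)) {
    dbg <- data.frame(
      time_s = est$time,
      X_m = est$main$X_m, Y_m = est$main$Y_m,
      x_s = est$sub$r_s[, 1], y_s = est$sub$r_s[, 2],
      R_sx = est$hip$R_s[, 1], R_sy = est$hip$R_s[, 2],
      R_sz = est$hip$R_s[, 3],
      N_sx = est$hip$N_s[, 1], N_sy = est$hip$N_s[, 2],
      theta_s1 = est$attitude$thigh$theta, phi_s1 = est$attitude$thigh$phi,
      psi_s1 = est$attitude$thigh$psi)
    utils::write.csv(dbg, file.path(cfg$out_dir, "debug.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(est$log, file.path(cfg$out_dir, "run.log"))
  invisible(est)
}

#' Validate an estimated COM CSV against a reference COM CSV
#'
#' Reads two COM CSVs, optionally aligns them by cross-correlation of the
#' anteroposterior channel (mirroring hardware synchronization by a shared
#' motion signature), and reports per-plane agreement metrics.
#'
#' @param estimate_csv,reference_csv COM CSV paths ([write_com_csv()]
#'   format).
#' @param window Evaluation window (sample indices in the estimate).
#' @param sync Align the reference to the estimate by cross-correlation
#'   before scoring.
#' @param max_lag_s Largest alignment shift considered \[s\] (at the
#'   estimate's sampling rate).
#'
#' @return List with `metrics_report`s `ap`, `ml` and the applied `lag`
#'   (samples; positive means the reference led the estimate).
#' @export
validate_files <- function(estimate_csv, reference_csv, window = 1001:4000,
                           sync = FALSE, max_lag_s = 1) {
  est <- read_com_csv(estimate_csv)
  ref <- read_com_csv(reference_csv)
  n <- length(est$com$X_b)
  if (length(ref$com$X_b) != n) {
    stop("estimate and reference lengths differ", call. = FALSE)
  }
  lag <- 0L
  if (isTRUE(sync)) {
    fs <- 1 / stats::median(diff(est$time))
    lag <- best_lag(est$com$X_b, ref$com$X_b, round(max_lag_s * fs))
    ref$com <- shift_com(ref$com, lag)
  }
  list(ap = com_metrics(est$com$X_b, ref$com$X_b, window),
       ml = com_metrics(est$com$Y_b, ref$com$Y_b, window),
       lag = lag)
}

# Lag maximizing the cross-correlation of mean-removed series; positive lag
# means `b` must be advanced (b leads a).
best_lag <- function(a, b, max_lag) {
  a <- a - mean(a)
  b <- b - mean(b)
  n <- length(a)
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(L) {
    ia <- max(1, 1 + L):min(n, n + L)
    ib <- ia - L
    sum(a[ia] * b[ib]) / length(ia)
  }, numeric(1))
  lags[which.max(score)]
}

# Apply the recovered lag: new[k] = old[k - lag], edges held.
shift_com <- function(com, lag) {
  shift1 <- function(x) {
    n <- length(x)
    if (lag == 0) return(x)
    if (lag > 0) c(rep(x[1], lag), x[1:(n - lag)])
    else c(x[(1 - lag):n], rep(x[n], -lag))
  }
  com_series(shift1(com$X_b), shift1(com$Y_b))
}
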