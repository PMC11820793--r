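# Shared fixtures: a mid-cohort subject and cached synthetic trials so the
# heavier closed-loop cases are generated once per file.

default_profile <- function(stance = "right") {
  subject_profile(1.73, 60.6, stance)
}

# evaluation window for 12 s module-test trials (3 s to 11 s)
quick_window <- 301:1100

.trial_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .trial_cache)) {
    assign(key, force(expr), envir = .trial_cache)
  }
  get(key, envir = .trial_cache)
}

# static balanced fixture: small whole-body lean, raised swing leg adducted
# towards the midline so the static COM offsets stay small
static_preset <- function(duration = 10) {
  motion_preset("A_quiet", duration = duration, ap_amp_mm = 0, ml_amp_mm = 0,
                wobble_deg = 0, main_pitch_offset_deg = 0.3,
                main_roll_offset_deg = 0.2, thigh_pitch_deg = 5,
                swing_roll_deg = 28.5)
}

rmse_mm <- function(a, b, w) 1000 * sqrt(mean((a[w] - b[w])^2))
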