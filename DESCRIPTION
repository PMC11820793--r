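Package: slscom
Title: Center-of-Mass Estimation for Single-Leg Standing from Force-Platform
    and Inertial Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates whole-body center-of-mass (COM) displacement during
    single-leg standing from a force platform and three inertial measurement
    units (head, non-stance thigh, non-stance lower leg). The stance leg and
    upper body are modelled as a linearized double-inverted pendulum in the
    sagittal and frontal planes; the non-stance leg is a two-link chain whose
    hip-joint force and moment are recovered by Newton-Euler inverse dynamics
    from IMU attitude estimates (extended Kalman filter for roll/pitch, rate
    integration for yaw). The package includes zero-phase filtering utilities,
    center-of-pressure computation, validation metrics against a reference COM
    trace, and a forward-kinematic synthetic trial generator that emits
    analytically consistent force-plate and IMU streams for closed-loop
    testing of the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
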