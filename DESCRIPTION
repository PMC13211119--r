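Package: zhcgait
Title: Foot Trajectory Reconstruction and Activity Recognition from a
    Foot-Mounted IMU
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stride-by-stride reconstruction of foot trajectories from a
    single foot-mounted inertial measurement unit. Each stride, bounded by
    detected zero-velocity points, is corrected by solving zero-velocity
    and zero-height-change constraints for a per-stride accelerometer bias
    and heel-strike velocity error; the latter drives adaptive five-class
    locomotion activity recognition (level ground, ramps, stairs), which
    selects the reconstruction mode. Provides gait-event detection, stride
    kinematic metrics, rigid-body toe-position estimation, and a synthetic
    gait simulator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
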