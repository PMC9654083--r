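Package: imugait
Title: Error-State Kalman Filtering of Body-Worn IMU Arrays for Lower-Limb Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates 3D lower-limb kinematics (hip, knee and ankle joint
    angles, per-stride ranges of motion, stride length and step width) from a
    seven-sensor array of body-worn inertial measurement units. A multi-body
    error-state Kalman filter propagates each sensor's position, velocity and
    orientation by strapdown integration and corrects integration drift with
    zero-velocity updates at footfalls, gravitational tilt corrections during
    still periods, joint-center coincidence constraints at all six joints and
    soft hinge (joint-axis alignment) corrections at the knees and hips.
    Includes gait event detection from raw gyroscope signals, sensor-to-segment
    calibration utilities, joint-coordinate-system angle decomposition, stride
    metric computation, and a kinematically consistent treadmill-gait simulator
    that synthesises IMU signals with exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
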