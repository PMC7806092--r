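Package: armfuse
Title: Magnetometer-Free Inertial-Robotic Fusion for Upper-Limb Motion Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensor fusion for end-effector-based rehabilitation robots
    augmented with a single wearable inertial measurement unit (IMU).
    Fuses body-frame gyroscope and accelerometer readings from an upper-arm
    IMU with robot-frame elbow position measurements to estimate, without
    any magnetometer, the drifting heading offset between the inertial and
    robot frames, the full upper-arm orientation, the elbow flexion angle,
    and the shoulder position in the robot workspace. Includes a rule-based
    detector of compensatory shoulder displacements for real-time
    biofeedback, and a kinematic simulator of cyclic planar arm motion that
    generates realistic IMU and robot measurement streams for testing and
    evaluation without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
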