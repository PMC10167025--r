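Package: strawbot
Title: Fiducial-Inertial Navigation and Counting-from-Video Yield
    Monitoring for Plant-Factory Inspection Robots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core of a plant-factory strawberry monitoring
    robot. Implements AprilTag-inertial (ATI) navigation: wheel-encoder/IMU
    dead reckoning, pose-graph mapping of ground fiducials with loop-closure
    optimisation (Levenberg-Marquardt), two-case localization, breadth-first
    path planning with virtual waypoints, and anti-windup PI velocity
    control. Implements a counting-from-video yield-monitoring pipeline:
    speed-aware keyframe-interval scheduling, selection of low-extraction-
    error keyframe sequences, distance and edge filtration of detections,
    and multi-sequence averaged fruit counting, with the associated accuracy
    metrics (RMSE positioning accuracy, relative counting and yield errors).
    A synthetic-world simulator generates tag layouts, noisy sensor logs and
    pinhole-projected fruit detection streams so the full stack is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
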