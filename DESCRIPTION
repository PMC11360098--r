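Package: neckwatch
Title: Sitting-Posture Abnormality Detection from Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detector-agnostic analysis of abnormal neck behaviour (head tilt
    and dropped head) in seated people from 2D pose keypoints in the
    OpenPose/COCO-18 layout. Provides keypoint geometry with camera-yaw
    estimation and foreshortening correction, an extended-Kalman-filter
    single-object tracker that bridges detector dropouts with
    difference-hash appearance matching, temporal event logic with
    multi-node fusion and alerting, a synthetic 3D-skeleton and
    tracking-sequence generator for end-to-end testing, and an evaluation
    harness reporting precision, recall and accuracy per camera position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    png,
    optparse
Config/testthat/edition: 3
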