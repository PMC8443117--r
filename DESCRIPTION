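Package: gaitpose
Title: Markerless Gait Analysis from 2D Pose Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns per-frame 2D body keypoints from markerless pose trackers
    (OpenPose, AlphaPose, Detectron) recorded from frontal-view walking video
    into spatiotemporal gait variables, and validates them against a reference
    motion-capture-style stream. The pipeline covers confidence-based masking
    and linear interpolation, left/right label-swap correction, zero-phase
    Butterworth smoothing, cropping to straight-walking bouts, foot-strike
    detection from the detrended vertical ankle trajectory, and computation of
    cadence, step time, step width, their coefficients of variation, and an
    estimated lateral margin of stability based on the extrapolated centre of
    mass. A statistics layer provides Pearson correlation grids across
    tracker/camera/view/method conditions, precision tables, and Bland-Altman
    agreement analysis. A seeded kinematic gait simulator generates paired
    ground-truth and corrupted keypoint streams so the whole pipeline is
    testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
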