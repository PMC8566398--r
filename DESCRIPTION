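Package: gammadex
Title: Marker-Based Instrument Tracking and Dexterity Analysis for
    Robot-Assisted Radioguided Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating gamma-probe guided robotic surgery from
    endoscopic video. Provides a pinhole camera model with checkerboard
    calibration, color/shape segmentation of cyan rectangle and yellow
    ring-triplet instrument markers, monocular pose estimation of the
    instrument tip, trajectory preprocessing (gap interpolation, median
    filtering), trial-level kinematic and dexterity metrics (path length,
    straightness index, angular dispersion, speed, acceleration, curvature,
    jerk), percentage-of-time occupancy density maps, and a logistic
    regression dexterity score. A synthetic-data module renders marker
    frames with ground-truth poses and simulates phantom pick-and-place
    trials and radioguided target-search trials under a Poisson counting
    probe model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
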