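Package: foveastrain
Title: Eyestrain Quantification on Stereoscopic Displays via Blink Rate
    and Foveated Image Factors
Version: 0.1.0
Authors@R:
    person("Foveastrain", "Developers", email = "foveastrain@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying visual fatigue on anaglyph (red-green)
    stereoscopic displays from a glasses-mounted near-infrared eye camera.
    Implements circular-edge pupil detection with local-binarization
    refinement, corneal specular-reflection detection and homography-based
    gaze mapping with one-point kappa calibration, blink detection by
    dark-pixel counting, an edge-refined foveation contrast-sensitivity
    mask in a four-level Daubechies wavelet domain, per-frame eyestrain
    factors (change of stereoscopic disparity, stereoscopic disparity,
    frame-cancellation effect, edge component) from red-green stereo
    frames, and the windowed correlation, 2^k factorial-design, Cohen's d
    and paired t-test statistics that relate the factors to blink rate.
    A deterministic synthetic-scene generator provides eye-image and
    anaglyph sequences with ground truth so the whole pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
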