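# foveastrain

Quantify eyestrain on anaglyph (red–green) stereoscopic displays from a
glasses-mounted near-infrared eye camera.

Viewer fatigue shows up as an elevated blink rate. `foveastrain` implements
the full measurement chain that relates windowed blink rate to four
candidate strain factors of the displayed 3-D content, each measured through
a *foveation contrast-sensitivity mask* — a per-sub-band weighting of a
4-level Daubechies wavelet decomposition centred on an edge-refined gaze
point, so that image content is weighted the way the retina resolves it:

| stage | what it does |
|---|---|
| eye tracking | circular-edge pupil detection + Otsu refinement, four corneal-glint detection, blink state from dark-pixel counts |
| gaze | glint-quad → monitor homography, one-point kappa calibration, gaze-error circle `N·v·tan(e)`, optional I-DT saccade suppression |
| foveation | 4-direction Sobel refinement of the gaze point, contrast-sensitivity mask `w = exp(−α f_λ ecc / e2)` in the wavelet domain |
| factors | CSD (change of stereoscopic disparity), SD, FCE `|W/2 − gaze_x|`, EC (Canny edge magnitude), from SAD block-matched disparity |
| statistics | 60 s windows stepped 10 s, min–max normalization, Pearson r / regression, 2^2 factorial design, Cohen's d, paired t-test |
| synthetic | deterministic eye-frame / anaglyph / scanpath generators with ground truth, so everything is testable offline |

## Worked example

The statistical battery on the four average blink-rate cell means of a
2×2 (SD × CSD) split:

```r
library(foveastrain)

f <- factorial_2k(0.4842, 0.5871, 0.4703, 0.4098)
sprintf("q0 = %.4f  qA = %.4f  qB = %.4f  qAB = %.4f", f$q0, f$qA, f$qB, f$qAB)
#> "q0 = 0.4878  qA = 0.0106  qB = -0.0478  qAB = -0.0408"
sprintf("effect ratios: SD %.2f%%  CSD %.2f%%  interaction %.2f%%",
        f$ratioA, f$ratioB, f$ratioAB)
#> "effect ratios: SD 2.76%  CSD 56.19%  interaction 41.04%"
```

CSD explains 56% of the blink-rate variation and SD under 3% — changes in
depth strain the viewer far more than depth itself. The standardized
difference between the two factors' per-user correlation summaries:

```r
d <- cohens_d(0.2841, 0.1730, -0.0299, 0.2368)
sprintf("Cohen's d = %.4f (%s)", d$d, d$label)
#> "Cohen's d = 1.5142 (large)"
```

End to end on synthetic data with a known linear blink/CSD coupling:

```r
ses   <- gen_coupled_session(duration_s = 120, seed = 7)
track <- track_eye_frames(ses$eye$frames, fps = 5, refine = FALSE)
gaze  <- data.frame(screen_x = rep(640, length(ses$video$frames)),
                    screen_y = rep(360, length(ses$video$frames)))
fac   <- factors_from_video(ses$video$frames, gaze, monitor = c(1280, 720),
                            fps = 2, compute = "csd")
res   <- session_stats(track, fac, fps_eye = 5)
sprintf("windows = %d, blink/CSD Pearson r = %.3f",
        nrow(res$blink), res$stats$csd$pearson_r)
#> "windows = 7, blink/CSD Pearson r = 1.000"
```

The generator schedules blinks and disparity switches from one event ramp,
so the recovered correlation should be (and is) essentially perfect.

## Command line

```sh
inst/cli/foveastrain simulate eye --seed 3 --duration 30 --fps 5 --out eye/
inst/cli/foveastrain track --eye-dir eye/ --fps 5 --out track.csv
inst/cli/foveastrain gaze --track track.csv --monitor 1280x720 \
    --calib-frame 0 --out gaze.csv
inst/cli/foveastrain factors --video-dir vid/ --gaze gaze.csv \
    --monitor 1280x720 --out factors.csv
inst/cli/foveastrain stats --blinks track.csv --factors factors.csv --out out/
```

## Documentation

The methods vignette (`vignettes/eyestrain-methods.Rmd`) describes the
models, parameter defaults and units, the synthetic world and what green
tests do and do not establish, numerical edge cases, and known limitations.
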