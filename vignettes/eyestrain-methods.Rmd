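---
title: "Quantifying eyestrain on stereoscopic displays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eyestrain on stereoscopic displays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveastrain)
```

## The measurement problem

Prolonged viewing of stereoscopic content fatigues the visual system, and
blink rate (BR) is a practical objective proxy: fatigued viewers blink more.
`foveastrain` implements a complete measurement chain for anaglyph
(red–green) stereo displays:

1. a glasses-mounted near-infrared eye camera yields gray frames in which
   the pupil is a dark disk and four monitor-corner illuminators leave four
   bright corneal glints;
2. pupil and glint positions give the on-screen gaze point through a
   projective transform, with a one-point calibration absorbing angle kappa;
3. a *foveation contrast-sensitivity mask*, centred on an edge-refined gaze
   point, reweights the display frames in a wavelet domain so that each
   candidate strain factor is measured the way the retina actually samples
   the scene;
4. four per-frame factors — change of stereoscopic disparity (CSD),
   stereoscopic disparity (SD), frame-cancellation effect (FCE), edge
   component (EC) — are accumulated in 60-second windows advanced by 10 s
   and related to windowed blink counts by correlation, regression, a 2^2
   factorial decomposition, Cohen's d, and a paired t-test.

Every stage is testable offline because a deterministic generator renders
synthetic eye sequences and anaglyph videos with known ground truth.

## Pupil, glints, blink

**Circular edge detection.** The pupil is located where the gray-level
difference between two adjacent circular templates is maximal. The package
defines the template at radius $r$ as the exact integer annulus
$\{(dx,dy): (r-\tfrac12)^2 \le dx^2+dy^2 < (r+\tfrac12)^2\}$ and scores
$\mathrm{mean}(\text{ring}_{r+2}) - \mathrm{mean}(\text{ring}_{r})$ over a
2-px center grid and all integer radii in the configured band, followed by a
1-px refinement around the best cell. The annulus definition involves only
integer arithmetic, so the fast C++ search and the brute-force R oracle used
in the tests select bit-identical pixel sets — an angularly sampled circle
does not have this property (nearest-pixel rounding of $r\cos\theta$ sits on
half-integer knife-edges that compilers resolve differently). Ties prefer the
smaller radius, then the smaller (y, x) center.

**Refinement.** Within a square window of side four initial radii the frame
is binarized with Otsu's threshold (parameter-free and robust for the
strongly bimodal pupil/iris window), components outside 0.3–3.0 times the
initial circle area are discarded, glint holes are closed morphologically,
and the component centroid becomes the refined center. The paper chain this
follows leaves all of these constants unstated; they are declared defaults,
all overridable.

**Blink.** A frame is *open* iff the number of pixels darker than gray 70 in
the pupil window reaches the open threshold (default 500; a count exactly at
threshold reads open). A blink is the closed-to-open transition, credited to
every window containing both frames; closings are not counted.

## Gaze mapping

The four glints mark the monitor corners, so the homography sending the
glint quadrilateral to the monitor rectangle maps the pupil center to screen
coordinates. Four correspondences determine the 8-parameter transform
exactly (direct linear solve); near-collinear quads raise a degeneracy
error. Gaze error of the underlying tracker is taken as $e = 1.12^\circ$
RMS, which on the image plane subtends a circle of radius

$$R = N\,v\,\tan e,$$

with $N$ the image width in pixels and $v$ the viewing distance in image
widths. Optional saccade suppression uses dispersion-based fixation
detection (I-DT): runs of at least 5 samples whose x-range + y-range stays
below 30 px collapse to their median position and transit samples snap to
the nearest fixation. The upstream "revised method" this stands in for is
not printed anywhere reproducible, so both parameters are exposed rather
than fixed.

## The foveation mask

Contrast sensitivity falls with eccentricity, faster at high spatial
frequency. For a 4-level Daubechies decomposition (db4 by default, db2
available) each sub-band coefficient at level $\lambda$ maps back to the
full-resolution point $2^\lambda x$, its distance $d$ from the foveation
point converts to eccentricity $\mathrm{ecc} = \arctan(d/(Nv))$ degrees, and
the weight is the sensitivity ratio

$$w = \exp\!\left(-\alpha\, f_\lambda\, \frac{\mathrm{ecc}}{e_2}\right),
\qquad \alpha = 0.106,\; e_2 = 2.3^\circ,$$

with $f_\lambda = f_d / 2^\lambda$ cycles/degree and
$f_d = \pi N v / 360$ the display Nyquist frequency (the deepest
approximation band uses $f_d/2^{\lambda_{\max}+1}$). The weight is 1 at the
gaze point and non-increasing with distance in every band; deep (low
frequency) bands decay more slowly, giving the familiar bright-centre
pyramid when the mask is rendered as a mosaic (`mask_mosaic()`). The
constants come from the foveated-coding literature the source chain cites;
the exact weight formula is not printed there, so per-coefficient values are
a declared model — the tests pin down structure (centre weight 1, radial
monotonicity, clipping to [0, 1]) rather than magic numbers.

**Edge refinement of the gaze point.** Within the gaze-error circle the
true gaze position is most likely where edge energy concentrates, so the
mask is centred on the pixel maximizing the total magnitude of four
directional 3×3 Sobel responses (0°, 45°, 90°, 135°), ties resolved toward
the raw point. With a constant image (no edges) the refined point equals the
raw point and the mask reduces to the unrefined baseline — the package
deliberately implements both variants as one construction differing only in
the point, which is what makes that equality hold exactly.

**Applying the mask.** The image is reflection-padded to a multiple of
$2^4$, transformed, multiplied band-wise, inverse-transformed, cropped and
clipped. The filter bank itself is *periodized* (circular) rather than
symmetric-extended: a non-redundant orthogonal transform with exact perfect
reconstruction is required for "unit mask = identity to 1e-6" to be a
meaningful acceptance bound, and periodization delivers it to machine
precision ($\sim 10^{-10}$ observed) while symmetric extension of an
orthogonal filter pair does not without redundant coefficients. Reflection
padding of the *image* still avoids the hard wrap-around seam at the frame
border.

## The four factors

- **Disparity** is estimated by SAD block matching (default 9×9 blocks,
  ±16 px search) on the green (left) and red (right) channels after mean
  brightness equalization. Cost ties resolve toward zero disparity, then
  the negative candidate, so untextured regions read 0; a left-right
  consistency check (tolerance 1 px) invalidates occluded pixels, which
  then contribute 0 to every sum. The matcher is written in-repo so the
  stage is oracle-testable against per-pixel exhaustive SAD.
- **SD** is the sum of absolute values of the foveation-masked disparity
  map, held in floating point throughout (no 8-bit requantization, avoiding
  quantization bias in CSD). The absolute value keeps SD non-negative when
  content carries signed (crossed/uncrossed) disparity.
- **CSD** is the sum of absolute differences between consecutive foveated
  disparity maps.
- **FCE** is $|W/2 - \text{gaze}_x|$ — the closer the gaze sits to a lateral
  display border, the stronger the occlusion conflict between the stereo
  half-images (e.g. gaze 20 on a 1280-px display gives 620; gaze 1270
  gives 630).
- **EC** runs a Canny detector (Gaussian 5×5 σ = 1.4, Sobel gradients,
  non-maximum suppression, 50/150 hysteresis) over both foveated
  half-images and adds the two sums of gradient magnitude over edge pixels.

## Windowing and statistics

Windows are $[t, t+60)$ s advanced by 10 s, giving
$\lfloor (T-60)/10 \rfloor + 1$ windows for a $T$-second recording (148 for
the 1530 s used as the reference session length, 3 for an 80 s clip). Blink
rate and each factor are min–max normalized to [0, 1] per user before any
cross-user averaging; a constant series maps to zeros by convention. The
battery is:

- Pearson r, the OLS slope of blink rate on the factor, and $R^2$;
- a 2^2 factorial decomposition of the four cell means obtained by
  splitting frames at the (max+min)/2 midpoint of SD and of CSD: the design
  solve is exact, $SS_\cdot = 4q_\cdot^2$, and effect ratios are
  $100\,SS_\cdot/SST$;
- Cohen's $d = |m_1-m_2| / \sqrt{(s_1^2+s_2^2)/2}$ (n-balanced pooled sd),
  labelled by the nearest of the 0.2/0.5/0.8 anchors — this labeller
  reproduces every published label in the reference effect-size tables,
  including the mixed assignments around 0.33–0.39;
- a paired two-tailed t-test with $n-1$ degrees of freedom for
  before/after subjective scores.

## The synthetic world

The generator states one world and the tests live in it:

- **Eye frames** (default 160×120 at 5 fps): anti-aliased pupil disk of
  radius 18 at gray 25 on a gray-190 background, four 3×3 glints at 255,
  additive Gaussian sensor noise of sd 2 gray levels. Closed intervals
  render a uniform gray-180 eyelid field, which drives the dark-pixel count
  to zero. These values sit in the regime of the real device the pipeline
  emulates (640×480 at 15 fps NIR imagery) while keeping the suite fast;
  the detectors are exercised at full resolution only through their own
  unit tests.
- **Anaglyph frames** (default 96×72 at 2 fps): band-limited uniform noise
  texture (box-smoothed, rescaled to [0, 255]) because block matching needs
  texture; the right view is the left view shifted by the scheduled
  disparity; scene changes regenerate the texture.
- **Coupled sessions**: one event schedule drives both streams — each
  10-second segment holds $k$ blinks *and* $k$ disparity switches between
  3 px and 6 px, with $k$ ramping over the session. Windowed blink rate and
  windowed CSD are then linearly related by construction, and the full
  pipeline (track → blink series → split → match → foveate → CSD → window →
  normalize → correlate) recovers r ≥ 0.9. The default acceptance session is
  180 s (13 windows) rather than the 25.5-minute reference session, purely
  a compute-budget scale-down; window geometry is unchanged.

What a green end-to-end test does *not* establish: performance on real
photographic content (texture statistics, shadows, eyelash occlusion,
specular clutter), robustness to head motion or calibration drift, and any
of the published human correlation magnitudes — those summarize recordings
that are not available, and the package deliberately replaces them with
parameter-recovery criteria.

## Numerical choices and edge cases

- CED tie-breaks: smaller radius, then smaller (y, x); refinement falls
  back to the unrefined result when no component survives.
- `blink_state` reads a count exactly at threshold as open.
- Disparity of flat image pairs is 0 by the tie rule, not invalid.
- `pair_and_normalize` maps constant windows to zeros; `correlate` refuses
  constant inputs instead of returning NaN.
- The factorial ratios are undefined at $SST = 0$ and raise a degenerate
  design error.
- All generators are bit-reproducible under a fixed seed; frames are
  integer-valued after rounding, so PGM round-trips are lossless.

## Known limitations

- Masks carry a single foveation point; multi-point saliency (colour,
  motion, intensity) is out of scope.
- The homography assumes the four glints and the pupil lie in one image
  plane; strong corneal curvature effects are absorbed only by the kappa
  offset.
- The saccade filter is an I-DT stand-in, not a reconstruction of the
  upstream micro-saccade model.
- Gaze is 2-D (screen position); vergence/accommodation are not estimated.
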