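## The foveation contrast-sensitivity mask: human contrast sensitivity is
## maximal at the gaze point and decays with eccentricity, faster at high
## spatial frequency. Each DWT sub-band is weighted by the sensitivity at
## its characteristic frequency and at the eccentricity of each coefficient,
## relative to the foveal value, so that multiplying the decomposition by
## the mask and inverting reproduces what the viewer actually resolves.
##
## The gaze point fed to the mask is first refined: within the gaze-error
## circle (radius N*v*tan(e)), the true gaze point is most likely where the
## edge response is strongest, so the point maximizing the total magnitude
## of four directional Sobel responses (TMSM) replaces the raw estimate.

#' Total directional Sobel magnitude (TMSM) at a point
#'
#' Sum over the four 3x3 Sobel masks (0, 45, 90, 135 degrees) of the
#' absolute filter response at `point`, with replicate border handling.
#'
#' @param image numeric matrix.
#' @param point (x, y), 1-based pixel coordinates.
#' @return non-negative scalar.
#' @export
sobel_tmsm <- function(image, point) {
  nr <- nrow(image); nc <- ncol(image)
  cx <- round(point[1]); cy <- round(point[2])
  fs_assert(cx >= 1 && cx <= nc && cy >= 1 && cy <= nr,
            "fs_degenerate_input", "point outside image")
  rs <- pmin(nr, pmax(1, (cy - 1):(cy + 1)))
  cs <- pmin(nc, pmax(1, (cx - 1):(cx + 1)))
  nb <- image[rs, cs, drop = FALSE]
  sum(vapply(sobel_kernels(), function(k) abs(sum(k * nb)), 0))
}

## TMSM over the whole image (vectorized through the conv kernel).
tmsm_map <- function(image) {
  maps <- lapply(sobel_kernels(), function(k) abs(conv2_replicate(image, k)))
  Reduce(`+`, maps)
}

#' Refine the gaze point to the strongest edge inside the gaze-error circle
#'
#' Evaluates TMSM at every pixel strictly closer to `xf` than `radius` and
#' returns the argmax; ties prefer the smaller distance to `xf`, then the
#' lexicographically smaller (y, x). With no candidate (radius 0) or a
#' constant image the raw point is returned.
#'
#' @param image numeric matrix.
#' @param xf raw gaze point (x, y), 1-based.
#' @param radius gaze-error circle radius in pixels (see [gaze_circle()]).
#' @return a `foveation_point` list: `xf`, `xcf`, `tmsm`.
#' @export
refine_foveation_point <- function(image, xf, radius) {
  nr <- nrow(image); nc <- ncol(image)
  fs_assert(xf[1] >= 1 && xf[1] <= nc && xf[2] >= 1 && xf[2] <= nr,
            "fs_degenerate_input", "xf outside image")
  if (radius <= 0)
    return(structure(list(xf = xf, xcf = xf, tmsm = sobel_tmsm(image, xf)),
                     class = "foveation_point"))
  cs <- max(1, ceiling(xf[1] - radius)):min(nc, floor(xf[1] + radius))
  rs <- max(1, ceiling(xf[2] - radius)):min(nr, floor(xf[2] + radius))
  tm <- tmsm_map(image)
  grid <- expand.grid(y = rs, x = cs)
  d <- sqrt((grid$x - xf[1])^2 + (grid$y - xf[2])^2)
  inside <- d < radius
  if (!any(inside))
    return(structure(list(xf = xf, xcf = xf, tmsm = sobel_tmsm(image, xf)),
                     class = "foveation_point"))
  g <- grid[inside, ]; d <- d[inside]
  val <- tm[cbind(g$y, g$x)]
  ## argmax with ties by distance, then (y, x)
  ord <- order(-val, d, g$y, g$x)
  best <- ord[1]
  structure(list(xf = xf, xcf = c(g$x[best], g$y[best]), tmsm = val[best]),
            class = "foveation_point")
}

#' Foveal contrast-sensitivity ratio
#'
#' `CS(f, ecc) / CS(f, 0) = exp(-alpha * f * ecc / e2)`, the standard
#' exponential falloff of contrast sensitivity with eccentricity used in
#' foveated image coding; `alpha = 0.106`, `e2 = 2.3` degrees.
#'
#' @param f spatial frequency in cycles/degree.
#' @param ecc eccentricity in degrees.
#' @param alpha,e2 model constants.
#' @return weight in `(0, 1]`.
#' @export
cs_weight <- function(f, ecc, alpha = 0.106, e2 = 2.3) {
  exp(-alpha * f * ecc / e2)
}

#' Build the foveation weighting mask for a 4-level wavelet decomposition
#'
#' For each coefficient of each sub-band the distance to the refined gaze
#' point is measured at full resolution (coefficient `(r, c)` of level `l`
#' maps to pixel `((c-1)*2^l, (r-1)*2^l)`, 0-based), converted to
#' eccentricity `atan(d / (N*v))`, and weighted by [cs_weight()] at the
#' sub-band's characteristic frequency `f_l = f_d / 2^l`, where
#' `f_d = pi * N * v / 360` cycles/degree is the display Nyquist frequency.
#' The deepest approximation band uses `f_d / 2^(levels+1)`.
#'
#' @param image_shape integer (nrows, ncols) of the image the mask is for.
#' @param point foveation point (x, y), 1-based full-resolution pixels;
#'   typically the `xcf` of [refine_foveation_point()].
#' @param N image width in pixels entering the eccentricity model.
#' @param v viewing distance in image widths.
#' @param levels decomposition depth.
#' @param wavelet wavelet name, must match the one used in [apply_mask()].
#' @param alpha,e2 contrast-sensitivity constants (see [cs_weight()]).
#' @return a `foveation_mask` with the same layout as [dwt2()] plus the
#'   geometry needed to check compatibility.
#' @export
build_mask <- function(image_shape, point, N, v, levels = 4L,
                       wavelet = "db4", alpha = 0.106, e2 = 2.3) {
  pad <- padded_shape(image_shape, levels)
  f_d <- pi * N * v / 360
  band_weights <- function(lev, f) {
    nr <- pad[1] %/% 2^lev; nc <- pad[2] %/% 2^lev
    xs <- (seq_len(nc) - 1) * 2^lev - (point[1] - 1)
    ys <- (seq_len(nr) - 1) * 2^lev - (point[2] - 1)
    d <- sqrt(outer(ys^2, xs^2, `+`))
    ecc <- atan(d / (N * v)) * 180 / pi
    clip01(cs_weight(f, ecc, alpha, e2))
  }
  detail <- vector("list", levels)
  for (lev in seq_len(levels)) {
    w <- band_weights(lev, f_d / 2^lev)
    detail[[lev]] <- list(HL = w, LH = w, HH = w)
  }
  structure(list(LL = band_weights(levels, f_d / 2^(levels + 1)),
                 detail = detail, levels = levels, wavelet = wavelet,
                 dim = as.integer(image_shape), pad_dim = pad,
                 point = point, N = N, v = v),
            class = "foveation_mask")
}

padded_shape <- function(image_shape, levels) {
  blk <- 2L^levels
  as.integer(image_shape + (blk - image_shape %% blk) %% blk)
}

#' Apply a foveation mask to an image through the wavelet domain
#'
#' Forward DWT, per-sub-band multiplication by the mask weights, inverse
#' DWT, then clipping to `clip`.
#'
#' @param image numeric matrix whose shape matches the mask's `dim`.
#' @param mask a `foveation_mask` from [build_mask()].
#' @param clip length-2 clipping range; use `range(image)` for non-8-bit
#'   rasters such as disparity maps.
#' @return matrix of the same shape as `image`.
#' @export
apply_mask <- function(image, mask, clip = c(0, 255)) {
  fs_assert(all(dim(image) == mask$dim), "fs_shape_error",
            "mask was built for a different image shape")
  p <- pad_for_dwt(image, mask$levels)
  w <- dwt2(p$img, levels = mask$levels, wavelet = mask$wavelet)
  w$LL <- w$LL * mask$LL
  for (lev in seq_len(w$levels))
    for (b in c("LH", "HL", "HH"))
      w$detail[[lev]][[b]] <- w$detail[[lev]][[b]] * mask$detail[[lev]][[b]]
  rec <- idwt2(w)[seq_len(p$nr), seq_len(p$nc), drop = FALSE]
  clip_range(rec, clip)
}

#' Identity (all-ones) mask with the layout of [build_mask()]
#'
#' @inheritParams build_mask
#' @return a `foveation_mask` whose every weight is 1.
#' @export
unit_mask <- function(image_shape, levels = 4L, wavelet = "db4") {
  pad <- padded_shape(image_shape, levels)
  ones <- function(lev) matrix(1, pad[1] %/% 2^lev, pad[2] %/% 2^lev)
  detail <- lapply(seq_len(levels), function(lev)
    list(HL = ones(lev), LH = ones(lev), HH = ones(lev)))
  structure(list(LL = ones(levels), detail = detail, levels = levels,
                 wavelet = wavelet, dim = as.integer(image_shape),
                 pad_dim = pad, point = NULL, N = NA, v = NA),
            class = "foveation_mask")
}
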