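## Per-frame eyestrain factors from red-green anaglyph frames:
##  SD  - stereoscopic disparity: sum of the foveation-masked disparity map;
##  CSD - change of SD: sum of |current - previous| foveated disparity maps;
##  FCE - frame-cancellation effect: |W/2 - gaze_x|, distance of the gaze
##        from the horizontal midline (border conflicts strain the viewer
##        when gaze sits near a screen edge);
##  EC  - edge component: summed Canny edge magnitude of the two foveated
##        half-images.

#' Split an anaglyph frame into its stereo half-images
#'
#' The green channel carries the left view, the red channel the right view.
#'
#' @param frame numeric array `nr x nc x 3` (RGB).
#' @return list with `left` and `right` gray matrices.
#' @export
split_anaglyph <- function(frame) {
  fs_assert(length(dim(frame)) == 3 && dim(frame)[3] == 3,
            "fs_channel_error", "anaglyph frame must have 3 channels")
  list(left = frame[, , 2], right = frame[, , 1])
}

#' Equalize the mean gray level of the two half-images
#'
#' Gray-level asymmetry between the channels biases the matching cost, so
#' the right image is rescaled to the left image's mean (then clipped to
#' `[0, 255]`).
#'
#' @param pair list with `left`, `right` matrices.
#' @return pair with adjusted `right`.
#' @export
normalize_brightness <- function(pair) {
  ml <- mean(pair$left); mr <- mean(pair$right)
  if (mr == 0) {
    if (ml == 0) return(pair)                 # both blank: no-op
    fs_error("fs_zero_image", "right image is all zero; cannot rescale")
  }
  pair$right <- clip_range(pair$right * (ml / mr), c(0, 255))
  pair
}

#' Dense horizontal disparity by SAD block matching
#'
#' For each left pixel the disparity `d` in `[-search_range, search_range]`
#' minimizing the sum of absolute differences between the left block at
#' `(r, c)` and the right block at `(r, c - d)` is selected (ties toward 0,
#' then the negative candidate; a flat untextured pair therefore reads 0).
#' A left-right consistency check (tolerance 1 px) marks occluded or
#' ambiguous pixels `NA`, as are border pixels where no block fits.
#'
#' @param pair list with `left`, `right` matrices of equal shape.
#' @param block odd block side, >= 3.
#' @param search_range maximum absolute disparity in pixels.
#' @param lr_check run the left-right consistency test.
#' @return matrix of disparities with `NA` for invalid pixels.
#' @export
compute_disparity <- function(pair, block = 9L, search_range = 16L,
                              lr_check = TRUE) {
  fs_assert(block %% 2 == 1 && block >= 3, "fs_degenerate_input",
            "block must be odd and >= 3")
  fs_assert(all(dim(pair$left) == dim(pair$right)), "fs_shape_error",
            "left/right shapes differ")
  dL <- cpp_sad_disparity(pair$left, pair$right, as.integer(block),
                          as.integer(search_range))
  if (!lr_check) return(dL)
  ## disparity seen from the right image, same sign convention
  dR <- -cpp_sad_disparity(pair$right, pair$left, as.integer(block),
                           as.integer(search_range))
  nr <- nrow(dL); nc <- ncol(dL)
  idx <- which(!is.na(dL), arr.ind = TRUE)
  cc <- idx[, 2] - dL[idx]
  ok <- cc >= 1 & cc <= nc
  back <- rep(NA_real_, nrow(idx))
  back[ok] <- dR[cbind(idx[ok, 1], cc[ok])]
  bad <- is.na(back) | abs(back - dL[idx]) > 1
  dL[idx[bad, , drop = FALSE]] <- NA_real_
  dL
}

#' Stereoscopic-disparity factor: sum of the foveated disparity map
#'
#' Invalid pixels contribute zero; the disparity raster stays floating
#' point through the mask (no 8-bit requantization).
#'
#' @param disparity matrix from [compute_disparity()].
#' @param mask `foveation_mask` built for the disparity shape.
#' @return non-negative scalar (absolute disparities are summed).
#' @export
compute_sd <- function(disparity, mask) {
  fov <- foveate_disparity(disparity, mask)
  sum(abs(fov))
}

## Shared path: zero-fill invalid pixels, apply the mask in the wavelet
## domain, clip to the raster's own range.
foveate_disparity <- function(disparity, mask) {
  d <- disparity
  d[is.na(d)] <- 0
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-1, 1)       # constant map: no-op clip
  apply_mask(d, mask, clip = rng)
}

#' Change-of-disparity factor: sum of absolute frame-to-frame differences
#'
#' @param prev_foveated,curr_foveated foveated disparity rasters of equal
#'   shape (successive frames).
#' @return non-negative scalar.
#' @export
compute_csd <- function(prev_foveated, curr_foveated) {
  fs_assert(all(dim(prev_foveated) == dim(curr_foveated)), "fs_shape_error",
            "raster shapes differ")
  sum(abs(curr_foveated - prev_foveated))
}

#' Frame-cancellation-effect factor
#'
#' `|monitor_width / 2 - gaze_x|`: zero at the screen midline, maximal when
#' the gaze reaches a lateral border where stereo occlusion conflicts live.
#'
#' @param gaze_x gaze X position in monitor pixels.
#' @param monitor_width horizontal monitor resolution.
#' @return distance in pixels.
#' @export
compute_fce <- function(gaze_x, monitor_width) {
  abs(monitor_width / 2 - gaze_x)
}

#' Edge-component factor: summed Canny edge magnitude of both half-images
#'
#' Runs the Canny detector on each foveated half-image, sums the gradient
#' magnitude over the surviving edge pixels of each, and adds the two sums.
#'
#' @param left_foveated,right_foveated foveated gray matrices.
#' @param canny_low,canny_high hysteresis thresholds on the Sobel gradient
#'   magnitude (8-bit scale).
#' @return non-negative scalar.
#' @export
compute_ec <- function(left_foveated, right_foveated,
                       canny_low = 50, canny_high = 150) {
  fs_assert(all(dim(left_foveated) == dim(right_foveated)), "fs_shape_error",
            "raster shapes differ")
  canny_magnitude_sum(left_foveated, canny_low, canny_high) +
    canny_magnitude_sum(right_foveated, canny_low, canny_high)
}

#' Canny edge detection
#'
#' Gaussian smoothing (5x5, sigma 1.4), Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, double threshold and
#' hysteresis (weak pixels survive only in 8-connected components touching
#' a strong pixel).
#'
#' @param image numeric matrix.
#' @param low,high hysteresis thresholds on gradient magnitude.
#' @return list with logical `edges` and numeric `magnitude` matrices.
#' @export
canny_edges <- function(image, low = 50, high = 150) {
  sm <- conv2_replicate(image, gaussian_kernel(5L, 1.4))
  k <- sobel_kernels()
  gx <- conv2_replicate(sm, k[[1]])
  gy <- conv2_replicate(sm, k[[3]])
  mag <- sqrt(gx^2 + gy^2)
  ## quantize direction to 0/45/90/135 and suppress non-maxima
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- (floor((ang + 22.5) / 45) %% 4) + 1   # 1:0deg 2:45 3:90 4:135
  offs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))  # (dy, dx) per sector
  nms <- mag
  for (s in 1:4) {
    o <- offs[[s]]
    fwd <- shift_mat(mag, -o[1], -o[2], 0)
    bwd <- shift_mat(mag, o[1], o[2], 0)
    sup <- sector == s & (mag < fwd | mag < bwd)
    nms[sup] <- 0
  }
  strong <- nms >= high
  weak <- nms >= low & !strong
  if (any(strong)) {
    lab <- label_components(strong | weak)
    good <- unique(lab[strong])
    edges <- lab > 0 & lab %in% good
  } else {
    edges <- strong
  }
  list(edges = edges, magnitude = mag)
}

canny_magnitude_sum <- function(image, low, high) {
  ce <- canny_edges(image, low, high)
  sum(ce$magnitude[ce$edges])
}
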