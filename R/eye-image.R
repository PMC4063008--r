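## Pupil, specular-reflection (SR) and eye-state detection in near-infrared
## eye-camera frames. The pupil appears as a dark disk; the four NIR
## illuminators on the monitor corners appear as four bright glints.

#' Detect the pupil by circular edge detection (CED)
#'
#' Finds the circle maximizing the gray-level difference between two adjacent
#' circular templates: score(c, r) = mean ring(r + 2) - mean ring(r), where
#' ring(r) is the 1-px-wide integer annulus
#' `(r - 0.5)^2 <= dx^2 + dy^2 < (r + 0.5)^2` around the center. The
#' search runs over integer radii in `[radius_min, radius_max]` and circle
#' centers on a `grid_step`-pixel grid (outer ring kept inside the frame),
#' then refines the best center at 1-px resolution. Ties prefer the smaller
#' radius, then the smaller (y, x) center.
#'
#' @param frame numeric matrix, gray values in `[0, 255]`.
#' @param radius_min,radius_max radius search band in pixels.
#' @param grid_step coarse center-grid step in pixels (default 2).
#' @param min_contrast minimum ring contrast (gray levels) below which no
#'   pupil is reported (closed eye / bad frame).
#' @param dark_cutoff gray level below which a pixel counts as "black" for
#'   the blink statistic.
#' @return a `pupil_result` list: `center` (x, y), `radius`, `score`,
#'   `black_pixel_count`, `refined = FALSE`.
#' @export
detect_pupil_ced <- function(frame, radius_min = 8L, radius_max = NULL,
                             grid_step = 2L, min_contrast = 10,
                             dark_cutoff = 70) {
  nr <- nrow(frame); nc <- ncol(frame)
  fs_assert(nr >= 8 && nc >= 8, "fs_degenerate_input", "frame too small")
  if (is.null(radius_max)) radius_max <- floor(min(nr, nc) / 2) - 3L
  fs_assert(radius_min >= 3, "fs_degenerate_input", "radius_min must be >= 3")
  fs_assert(radius_max >= radius_min, "fs_degenerate_input",
            "radius_max below radius_min")
  coarse <- cpp_ced_search(frame, as.integer(radius_min),
                           as.integer(radius_max), as.integer(grid_step),
                           0L, 0L, nc - 1L, nr - 1L)
  if (!is.finite(coarse$score) || coarse$score < min_contrast)
    fs_error("fs_no_pupil", "no circular pupil boundary above contrast floor")
  fine <- cpp_ced_search(frame, as.integer(coarse$r), as.integer(coarse$r),
                         1L, coarse$x - grid_step, coarse$y - grid_step,
                         coarse$x + grid_step, coarse$y + grid_step)
  best <- if (is.finite(fine$score) && fine$score >= coarse$score) fine else coarse
  center <- c(best$x + 1, best$y + 1)             # to 1-based (x, y)
  win <- pupil_window(frame, center, best$r)
  structure(list(center = center, radius = best$r, score = best$score,
                 black_pixel_count = sum(win$pix < dark_cutoff),
                 refined = FALSE),
            class = "pupil_result")
}

## Square search window of side 4*radius around the center, clipped.
pupil_window <- function(frame, center, radius) {
  half <- 2L * as.integer(ceiling(radius))
  cx <- round(center[1]); cy <- round(center[2])
  rs <- max(1, cy - half):min(nrow(frame), cy + half)
  cs <- max(1, cx - half):min(ncol(frame), cx + half)
  list(pix = frame[rs, cs, drop = FALSE], rows = rs, cols = cs)
}

#' Refine a pupil detection by local binarization and centroid
#'
#' Inside a square window of side four initial radii: threshold with Otsu's
#' method, label dark components, keep those whose area lies within
#' `size_band * pi * r^2`, pick the surviving component closest to the
#' initial center, fill SR holes by morphological closing, and return the
#' centroid of the filled component.
#'
#' @param frame numeric matrix.
#' @param initial a `pupil_result` from [detect_pupil_ced()].
#' @param size_band area band relative to the initial circle area.
#' @param dark_cutoff gray cutoff used for the black-pixel count.
#' @return a refined `pupil_result` (`refined = TRUE`).
#' @export
refine_pupil <- function(frame, initial, size_band = c(0.3, 3.0),
                         dark_cutoff = 70) {
  fs_assert(inherits(initial, "pupil_result"), "fs_degenerate_input",
            "initial must be a pupil_result")
  win <- pupil_window(frame, initial$center, initial$radius)
  thr <- otsu_threshold(win$pix)
  dark <- win$pix < thr
  labels <- label_components(dark)
  stats <- component_stats(labels)
  area0 <- pi * initial$radius^2
  keep <- stats[stats$area >= size_band[1] * area0 &
                stats$area <= size_band[2] * area0, , drop = FALSE]
  if (nrow(keep) == 0)
    fs_error("fs_refinement_failed", "no pupil-sized dark component in window")
  ## component nearest the initial center (window coordinates)
  cx0 <- initial$center[1] - win$cols[1] + 1
  cy0 <- initial$center[2] - win$rows[1] + 1
  d2 <- (keep$cx - cx0)^2 + (keep$cy - cy0)^2
  sel <- keep$id[which.min(d2)]
  filled <- close_mask(labels == sel, iterations = 2L)
  idx <- which(filled, arr.ind = TRUE)
  center <- c(mean(idx[, 2]) + win$cols[1] - 1, mean(idx[, 1]) + win$rows[1] - 1)
  radius <- sqrt(nrow(idx) / pi)
  structure(list(center = center, radius = radius, score = initial$score,
                 black_pixel_count = sum(win$pix < dark_cutoff),
                 refined = TRUE),
            class = "pupil_result")
}

#' Detect the four corneal specular reflections around the pupil
#'
#' Bright pixels (`> bright_cutoff`) in a square region around the pupil
#' center are labelled; components within `size_band` survive; exactly four
#' must remain. Their centroids are returned ordered top-left, top-right,
#' bottom-right, bottom-left by angular position around the common centroid.
#'
#' @param frame numeric matrix.
#' @param pupil a `pupil_result`.
#' @param region_half half-side of the search region in pixels (default
#'   covers the whole frame).
#' @param bright_cutoff gray level above which a pixel is a glint candidate.
#' @param size_band admissible component area range in pixels.
#' @return an `sr_quad`: 4x2 matrix of (x, y) rows in TL, TR, BR, BL order.
#' @export
detect_srs <- function(frame, pupil, region_half = NULL, bright_cutoff = 230,
                       size_band = c(2, 400)) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(region_half)) region_half <- max(nr, nc)
  cx <- round(pupil$center[1]); cy <- round(pupil$center[2])
  rs <- max(1, cy - region_half):min(nr, cy + region_half)
  cs <- max(1, cx - region_half):min(nc, cx + region_half)
  bright <- frame[rs, cs, drop = FALSE] > bright_cutoff
  stats <- component_stats(label_components(bright))
  stats <- stats[stats$area >= size_band[1] & stats$area <= size_band[2], ,
                 drop = FALSE]
  if (nrow(stats) != 4)
    fs_error("fs_sr_count",
             sprintf("expected 4 specular reflections, found %d", nrow(stats)))
  pts <- cbind(x = stats$cx + cs[1] - 1, y = stats$cy + rs[1] - 1)
  order_quad(pts)
}

## Order 4 points TL, TR, BR, BL by angle around their centroid
## (y grows downward, so TL sits near angle -3*pi/4).
order_quad <- function(pts) {
  ang <- atan2(pts[, 2] - mean(pts[, 2]), pts[, 1] - mean(pts[, 1]))
  key <- (ang + 3 * pi / 4) %% (2 * pi)
  out <- pts[order(key), , drop = FALSE]
  rownames(out) <- c("TL", "TR", "BR", "BL")
  class(out) <- c("sr_quad", class(out))
  out
}

#' Classify the eye as open or closed from the dark-pixel count
#'
#' Counts pixels darker than `dark_cutoff` in the region; the eye is open
#' iff the count is at least `open_threshold` (a count exactly equal to the
#' threshold reads as open).
#'
#' @param region numeric matrix (the pupil search window).
#' @param open_threshold minimum dark-pixel count for an open eye.
#' @param dark_cutoff gray level below which a pixel is "black".
#' @return list with `state` ("open"/"closed") and `black_pixel_count`.
#' @export
blink_state <- function(region, open_threshold = 500L, dark_cutoff = 70) {
  fs_assert(open_threshold > 0, "fs_degenerate_input",
            "open_threshold must be positive")
  n <- sum(region < dark_cutoff)
  list(state = if (n >= open_threshold) "open" else "closed",
       black_pixel_count = n)
}
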