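## Gaze mapping: the four corneal glints mark the monitor corners in the eye
## image, so the projective transform sending the glint quadrilateral to the
## monitor rectangle carries the pupil center to the on-screen gaze point.
## A one-point calibration at the screen center absorbs angle kappa (the
## offset between visual and pupillary axes).

#' Homography from four point correspondences
#'
#' Solves the 8-unknown direct linear system exactly.
#'
#' @param src,dst 4x2 matrices of (x, y) rows.
#' @return 3x3 homography matrix `H` with `H[3,3] = 1`.
#' @export
homography_from_quad <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    fs_error("fs_degenerate_quad", "SR quad is degenerate (collinear points)"))
  if (any(!is.finite(h)))
    fs_error("fs_degenerate_quad", "SR quad is degenerate (collinear points)")
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, pt) {
  v <- H %*% c(pt[1], pt[2], 1)
  if (abs(v[3]) < 1e-12)
    fs_error("fs_degenerate_quad", "point maps to infinity under homography")
  c(v[1] / v[3], v[2] / v[3])
}

#' Map a pupil center to monitor coordinates via the SR quad
#'
#' Computes the projective transform sending the SR quadrilateral to the
#' monitor corner rectangle `(0,0), (W-1,0), (W-1,H-1), (0,H-1)` and applies
#' it to the pupil center. Points falling outside the monitor rectangle by
#' more than `margin` (fraction of each dimension) are flagged invalid;
#' coordinates are clamped to the screen.
#'
#' @param pupil_center numeric (x, y).
#' @param srs 4x2 SR quad in TL, TR, BR, BL order (see [detect_srs()]).
#' @param monitor integer (width, height) in pixels.
#' @param kappa optional (dx, dy) offset from [calibrate_kappa()].
#' @param margin off-screen tolerance as a fraction of each dimension.
#' @return list with `screen` (x, y), `valid`, `raw` (pre-clamp position).
#' @export
map_gaze <- function(pupil_center, srs, monitor, kappa = c(0, 0),
                     margin = 0.05) {
  W <- monitor[1]; H <- monitor[2]
  corners <- rbind(c(0, 0), c(W - 1, 0), c(W - 1, H - 1), c(0, H - 1))
  Hm <- homography_from_quad(srs, corners)
  p <- apply_homography(Hm, pupil_center) + kappa
  valid <- p[1] >= -margin * W && p[1] <= (W - 1) + margin * W &&
           p[2] >= -margin * H && p[2] <= (H - 1) + margin * H
  screen <- c(min(W - 1, max(0, p[1])), min(H - 1, max(0, p[2])))
  list(screen = screen, valid = valid, raw = p)
}

#' One-point kappa calibration at the monitor center
#'
#' While the user fixates the screen center, the mapped gaze should land at
#' `(W/2, H/2)`; the returned offset moves it there and is added to every
#' subsequent [map_gaze()] output.
#'
#' @param mapped_center_gaze (x, y) mapped gaze during center fixation.
#' @param monitor (width, height) in pixels.
#' @return numeric (dx, dy).
#' @export
calibrate_kappa <- function(mapped_center_gaze, monitor) {
  c(monitor[1] / 2 - mapped_center_gaze[1],
    monitor[2] / 2 - mapped_center_gaze[2])
}

#' Radius of the gaze-error circle on the image plane
#'
#' The region containing the true gaze point, given tracker error `e`
#' degrees, has radius `N * v * tan(e)` pixels, where `N` is the image width
#' and `v` the viewing distance in image widths.
#'
#' @param N image width in pixels.
#' @param v viewing distance in image widths.
#' @param e gaze error half-angle in degrees.
#' @return radius in pixels.
#' @export
gaze_circle <- function(N, v, e) {
  fs_assert(N > 0 && v > 0 && e >= 0 && e < 90, "fs_degenerate_input",
            "need N > 0, v > 0, 0 <= e < 90")
  N * v * tan(e * pi / 180)
}

#' Suppress saccadic jitter by dispersion-based fixation detection
#'
#' I-DT style: a run of at least `window_frames` samples whose dispersion
#' (x range + y range) stays below `dispersion_px` is a fixation; every
#' sample in the run is replaced by the run's median position, and samples
#' in saccadic transit snap to the nearest (in time) fixation's median.
#'
#' @param xy n x 2 matrix of gaze positions (x, y), time-ordered.
#' @param window_frames minimum fixation length in samples.
#' @param dispersion_px dispersion threshold in pixels.
#' @return n x 2 matrix of smoothed positions.
#' @export
compensate_saccades <- function(xy, window_frames = 5L, dispersion_px = 30) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2) return(xy)
  run_id <- integer(n)                      # 0 = transit
  fix_med <- list()
  i <- 1L; nf <- 0L
  while (i + window_frames - 1L <= n) {
    j <- i + window_frames - 1L
    if (dispersion(xy[i:j, , drop = FALSE]) <= dispersion_px) {
      while (j < n && dispersion(xy[i:(j + 1L), , drop = FALSE]) <= dispersion_px)
        j <- j + 1L
      nf <- nf + 1L
      run_id[i:j] <- nf
      fix_med[[nf]] <- c(median(xy[i:j, 1]), median(xy[i:j, 2]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (nf == 0L) return(xy)                  # no fixation found: leave as-is
  out <- xy
  centers <- vapply(seq_len(nf), function(k) mean(which(run_id == k)), 0)
  for (t in seq_len(n)) {
    k <- if (run_id[t] > 0L) run_id[t] else which.min(abs(centers - t))
    out[t, ] <- fix_med[[k]]
  }
  out
}

dispersion <- function(xy) {
  (max(xy[, 1]) - min(xy[, 1])) + (max(xy[, 2]) - min(xy[, 2]))
}
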