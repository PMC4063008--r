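## Deterministic synthetic scenes with ground truth, emulating what the
## eye camera and the anaglyph display feed the pipeline:
##  - eye frames: dark anti-aliased pupil disk, four bright corneal glints,
##    scheduled blinks rendered as a uniform eyelid-gray field, Gaussian
##    sensor noise;
##  - anaglyph frames: band-limited noise texture (block matching needs
##    texture), the right view shifted horizontally by a scheduled
##    disparity, scene changes refreshing the texture;
##  - gaze scanpaths: jittered fixations joined by linear saccadic transits.
## Every generator is bit-reproducible under a fixed seed.

#' Specification of a synthetic eye-camera scene
#'
#' @param width,height frame size in pixels.
#' @param pupil_center (x, y) pupil position, or an `n x 2` per-frame
#'   trajectory.
#' @param pupil_radius pupil radius in pixels.
#' @param sr_layout 4x2 matrix of glint positions (TL, TR, BR, BL).
#' @param blink_schedule list of `c(close_t, open_t)` intervals in seconds
#'   (eye closed on `[close_t, open_t)`), non-overlapping and ordered.
#' @param noise_sd Gaussian sensor-noise standard deviation (gray levels).
#' @param bg_gray,pupil_gray,lid_gray background / pupil / closed-eyelid
#'   gray levels.
#' @param seed integer seed fixing the rendering exactly.
#' @return an `eye_scene_spec` list.
#' @export
eye_scene_spec <- function(width = 160L, height = 120L,
                           pupil_center = c(80, 60), pupil_radius = 18,
                           sr_layout = rbind(c(50, 35), c(110, 35),
                                             c(110, 85), c(50, 85)),
                           blink_schedule = list(),
                           noise_sd = 2, bg_gray = 190, pupil_gray = 25,
                           lid_gray = 180, seed = 1L) {
  if (length(blink_schedule) > 1) {
    m <- do.call(rbind, blink_schedule)
    fs_assert(all(m[, 2] > m[, 1]) && all(diff(as.vector(t(m))) > 0),
              "fs_spec_error", "blink intervals must be ordered, disjoint")
  }
  fs_assert(nrow(unique(sr_layout)) == 4, "fs_spec_error",
            "SR layout needs four distinct points")
  structure(list(width = width, height = height,
                 pupil_center = pupil_center, pupil_radius = pupil_radius,
                 sr_layout = sr_layout, blink_schedule = blink_schedule,
                 noise_sd = noise_sd, bg_gray = bg_gray,
                 pupil_gray = pupil_gray, lid_gray = lid_gray,
                 seed = as.integer(seed)),
            class = "eye_scene_spec")
}

## Anti-aliased disk: pixel value interpolates over the boundary band.
render_disk <- function(width, height, center, radius, fg, bg) {
  d <- sqrt(outer((seq_len(height) - center[2])^2,
                  (seq_len(width) - center[1])^2, `+`))
  cov <- clip01(radius + 0.5 - d)
  matrix(bg, height, width) * (1 - cov) + fg * cov
}

#' Render a synthetic eye-frame sequence
#'
#' @param spec an [eye_scene_spec()].
#' @param fps frame rate.
#' @param duration_s sequence length in seconds.
#' @return list with `frames` (list of matrices) and `truth` (data.frame
#'   with `frame_index`, `time_s`, `pupil_x`, `pupil_y`, `state`).
#' @export
gen_eye_sequence <- function(spec, fps = 15, duration_s = 10) {
  n <- as.integer(round(fps * duration_s))
  times <- (seq_len(n) - 1) / fps
  traj <- spec$pupil_center
  if (is.null(dim(traj))) traj <- matrix(traj, n, 2, byrow = TRUE)
  closed <- rep(FALSE, n)
  for (iv in spec$blink_schedule)
    closed <- closed | (times >= iv[1] & times < iv[2])
  set.seed(spec$seed)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    if (closed[i]) {
      img <- matrix(spec$lid_gray, spec$height, spec$width)
    } else {
      img <- render_disk(spec$width, spec$height, traj[i, ],
                         spec$pupil_radius, spec$pupil_gray, spec$bg_gray)
      for (k in 1:4) {
        x <- round(spec$sr_layout[k, 1]); y <- round(spec$sr_layout[k, 2])
        rs <- max(1, y - 1):min(spec$height, y + 1)
        cs <- max(1, x - 1):min(spec$width, x + 1)
        img[rs, cs] <- 255
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    frames[[i]] <- clip_range(round(img), c(0, 255))
  }
  truth <- data.frame(frame_index = seq_len(n) - 1L, time_s = times,
                      pupil_x = traj[, 1], pupil_y = traj[, 2],
                      state = ifelse(closed, "closed", "open"))
  list(frames = frames, truth = truth)
}

#' Specification of a synthetic anaglyph stereo scene
#'
#' The right view equals the left view shifted horizontally by the
#' scheduled disparity (positive disparity shifts content leftward in the
#' right view, the crossed/pop-out direction under the matching convention
#' of [compute_disparity()]).
#'
#' @param width,height frame size.
#' @param disparity_schedule either a single disparity (pixels) or a
#'   data.frame with columns `t` (seconds) and `d`: the disparity holds
#'   from each `t` until the next.
#' @param scene_change_times times (s) at which the background texture is
#'   regenerated.
#' @param texture_smooth half-width of the box smoothing applied to the
#'   white-noise texture (band-limits it so blocks stay matchable).
#' @param seed integer seed.
#' @return a `stereo_scene_spec` list.
#' @export
stereo_scene_spec <- function(width = 96L, height = 72L,
                              disparity_schedule = 4,
                              scene_change_times = numeric(0),
                              texture_smooth = 1L, seed = 1L) {
  if (is.data.frame(disparity_schedule))
    fs_assert(all(c("t", "d") %in% names(disparity_schedule)),
              "fs_spec_error", "disparity schedule needs columns t, d")
  structure(list(width = width, height = height,
                 disparity_schedule = disparity_schedule,
                 scene_change_times = scene_change_times,
                 texture_smooth = as.integer(texture_smooth),
                 seed = as.integer(seed)),
            class = "stereo_scene_spec")
}

## Seeded band-limited noise texture in [0, 255].
noise_texture <- function(width, height, smooth) {
  img <- matrix(runif(width * height), height, width)
  if (smooth > 0) {
    k <- matrix(1, 2 * smooth + 1, 2 * smooth + 1)
    img <- cpp_conv2_replicate(img, k / sum(k))
  }
  r <- range(img)
  (img - r[1]) / (r[2] - r[1]) * 255
}

## Shift columns rightward-content: out[, c] = img[, c + d], replicate edge.
shift_cols <- function(img, d) {
  nc <- ncol(img)
  src <- pmin(nc, pmax(1, seq_len(nc) + d))
  img[, src, drop = FALSE]
}

#' Render a synthetic anaglyph frame sequence
#'
#' @param spec a [stereo_scene_spec()].
#' @param fps frame rate.
#' @param duration_s sequence length in seconds.
#' @return list with `frames` (list of `nr x nc x 3` arrays) and `truth`
#'   (data.frame with `frame_index`, `time_s`, `disparity`,
#'   `scene_change`).
#' @export
gen_anaglyph_video <- function(spec, fps = 2, duration_s = 30) {
  n <- as.integer(round(fps * duration_s))
  times <- (seq_len(n) - 1) / fps
  ds <- spec$disparity_schedule
  disp <- if (is.data.frame(ds)) {
    idx <- findInterval(times, ds$t)
    fs_assert(all(idx >= 1), "fs_spec_error",
              "disparity schedule must start at or before t = 0")
    ds$d[idx]
  } else rep(ds, n)
  change <- rep(FALSE, n)
  for (tc in spec$scene_change_times) {
    i <- which(times >= tc)[1]
    if (!is.na(i)) change[i] <- TRUE
  }
  set.seed(spec$seed)
  tex <- noise_texture(spec$width, spec$height, spec$texture_smooth)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    if (change[i]) tex <- noise_texture(spec$width, spec$height,
                                        spec$texture_smooth)
    left <- tex
    right <- shift_cols(tex, as.integer(round(disp[i])))
    arr <- array(0, dim = c(spec$height, spec$width, 3L))
    arr[, , 1] <- right   # red carries the right view
    arr[, , 2] <- left    # green carries the left view
    frames[[i]] <- arr
  }
  truth <- data.frame(frame_index = seq_len(n) - 1L, time_s = times,
                      disparity = disp, scene_change = change)
  list(frames = frames, truth = truth)
}

#' Generate a jittered fixation/saccade gaze scanpath
#'
#' @param fixations data.frame with columns `x`, `y`, `duration`
#'   (seconds); fixations are visited in order with linear saccadic
#'   transits of `saccade_ms` between them.
#' @param saccade_ms transit duration in milliseconds.
#' @param fps sample rate.
#' @param jitter_sd Gaussian jitter added to fixation samples (pixels).
#' @param seed integer seed.
#' @return data.frame with `time_s`, `x`, `y`, `fixation_id` (0 during
#'   transit).
#' @export
gen_gaze_scanpath <- function(fixations, saccade_ms = 40, fps = 15,
                              jitter_sd = 0, seed = 1L) {
  fs_assert(all(fixations$duration > 0), "fs_spec_error",
            "fixation durations must be positive")
  set.seed(as.integer(seed))
  nf <- nrow(fixations)
  t <- 0; rows <- list()
  for (k in seq_len(nf)) {
    nsamp <- max(1L, as.integer(round(fixations$duration[k] * fps)))
    tt <- t + (seq_len(nsamp) - 1) / fps
    rows[[length(rows) + 1]] <- data.frame(
      time_s = tt,
      x = fixations$x[k] + rnorm(nsamp, 0, jitter_sd),
      y = fixations$y[k] + rnorm(nsamp, 0, jitter_sd),
      fixation_id = k)
    t <- t + fixations$duration[k]
    if (k < nf && saccade_ms > 0) {
      nsac <- as.integer(round(saccade_ms / 1000 * fps))
      if (nsac > 0) {
        frac <- seq_len(nsac) / (nsac + 1)
        rows[[length(rows) + 1]] <- data.frame(
          time_s = t + (seq_len(nsac) - 1) / fps,
          x = fixations$x[k] + frac * (fixations$x[k + 1] - fixations$x[k]),
          y = fixations$y[k] + frac * (fixations$y[k + 1] - fixations$y[k]),
          fixation_id = 0L)
        t <- t + nsac / fps
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
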