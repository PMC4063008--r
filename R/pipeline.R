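## End-to-end orchestration: track eye frames, map gaze, compute per-frame
## factors from the anaglyph stream, window everything and correlate.

#' Track pupil, glints and eye state over an eye-frame sequence
#'
#' Each frame is first classified open/closed by the dark-pixel count; the
#' pupil (and optionally the SR quad) is detected on open frames only.
#'
#' @param frames list of gray matrices (or a directory of PGM frames).
#' @param fps frame rate.
#' @param radius_band pupil radius search band in pixels.
#' @param open_threshold dark-pixel count at or above which the eye is open.
#' @param dark_cutoff gray level below which a pixel is "black".
#' @param refine run the local-binarization refinement on each detection.
#' @param srs also detect the four specular reflections per frame.
#' @return data.frame with per-frame `frame_index`, `timestamp_s`,
#'   `pupil_x`, `pupil_y`, `pupil_radius`, `black_count`, `state` and,
#'   when `srs`, `sr1_x` .. `sr4_y`.
#' @export
track_eye_frames <- function(frames, fps = 15, radius_band = c(8L, 30L),
                             open_threshold = 500L, dark_cutoff = 70,
                             refine = TRUE, srs = FALSE) {
  if (is.character(frames)) frames <- lapply(list_frames(frames), read_pgm)
  n <- length(frames)
  out <- data.frame(frame_index = seq_len(n) - 1L,
                    timestamp_s = (seq_len(n) - 1) / fps,
                    pupil_x = NA_real_, pupil_y = NA_real_,
                    pupil_radius = NA_real_, black_count = NA_integer_,
                    state = "closed", stringsAsFactors = FALSE)
  if (srs) for (k in 1:4) { out[[paste0("sr", k, "_x")]] <- NA_real_
                            out[[paste0("sr", k, "_y")]] <- NA_real_ }
  for (i in seq_len(n)) {
    bs <- blink_state(frames[[i]], open_threshold, dark_cutoff)
    out$black_count[i] <- bs$black_pixel_count
    out$state[i] <- bs$state
    if (bs$state == "closed") next
    pup <- tryCatch(
      detect_pupil_ced(frames[[i]], radius_band[1], radius_band[2],
                       dark_cutoff = dark_cutoff),
      fs_no_pupil = function(e) NULL)
    if (is.null(pup)) { out$state[i] <- "closed"; next }
    if (refine)
      pup <- tryCatch(refine_pupil(frames[[i]], pup,
                                   dark_cutoff = dark_cutoff),
                      fs_refinement_failed = function(e) pup)
    out$pupil_x[i] <- pup$center[1]
    out$pupil_y[i] <- pup$center[2]
    out$pupil_radius[i] <- pup$radius
    if (srs) {
      quad <- tryCatch(detect_srs(frames[[i]], pup), fs_sr_count = function(e) NULL)
      if (!is.null(quad))
        for (k in 1:4) { out[[paste0("sr", k, "_x")]][i] <- quad[k, 1]
                         out[[paste0("sr", k, "_y")]][i] <- quad[k, 2] }
    }
  }
  out
}

#' Map a tracking table to monitor gaze coordinates
#'
#' Uses the per-frame SR quad when present, otherwise a fixed quad (e.g.
#' from a calibration frame). Closed frames carry the previous valid gaze.
#'
#' @param track data.frame from [track_eye_frames()].
#' @param monitor (width, height) in pixels.
#' @param srs_fixed optional 4x2 quad used for all frames.
#' @param kappa (dx, dy) offset from [calibrate_kappa()].
#' @return data.frame with `timestamp_s`, `screen_x`, `screen_y`, `valid`.
#' @export
gaze_from_track <- function(track, monitor, srs_fixed = NULL,
                            kappa = c(0, 0)) {
  n <- nrow(track)
  out <- data.frame(timestamp_s = track$timestamp_s,
                    screen_x = NA_real_, screen_y = NA_real_,
                    valid = FALSE)
  last <- c(monitor[1] / 2, monitor[2] / 2)
  for (i in seq_len(n)) {
    if (!is.na(track$pupil_x[i])) {
      quad <- srs_fixed
      if (is.null(quad) && !is.null(track$sr1_x) && !is.na(track$sr1_x[i]))
        quad <- cbind(c(track$sr1_x[i], track$sr2_x[i],
                        track$sr3_x[i], track$sr4_x[i]),
                      c(track$sr1_y[i], track$sr2_y[i],
                        track$sr3_y[i], track$sr4_y[i]))
      if (!is.null(quad)) {
        g <- map_gaze(c(track$pupil_x[i], track$pupil_y[i]), quad,
                      monitor, kappa)
        out$screen_x[i] <- g$screen[1]; out$screen_y[i] <- g$screen[2]
        out$valid[i] <- g$valid
        if (g$valid) last <- g$screen
        next
      }
    }
    out$screen_x[i] <- last[1]; out$screen_y[i] <- last[2]
  }
  ## fill invalid/closed with last valid position
  for (i in seq_len(n))
    if (is.na(out$screen_x[i])) { out$screen_x[i] <- last[1]
                                  out$screen_y[i] <- last[2] }
  out
}

#' Per-frame eyestrain factors from an anaglyph sequence and gaze
#'
#' Gaze (monitor coordinates) is scaled to frame coordinates by the width
#' ratio, refined to the strongest edge inside the gaze-error circle, and
#' drives the foveation mask applied to the disparity map (SD, CSD) and,
#' when requested, to the half-images (EC).
#'
#' @param frames list of RGB arrays (or a directory of PPM frames).
#' @param gaze data.frame with `screen_x`, `screen_y` per frame (monitor
#'   coordinates), same length as `frames`.
#' @param monitor (width, height) of the display in pixels.
#' @param fps frame rate of the sequence.
#' @param v viewing distance in image widths.
#' @param e gaze-error half-angle in degrees.
#' @param block,search_range block-matching parameters.
#' @param compute subset of `c("csd", "sd", "fce", "ec")`.
#' @param canny_low,canny_high Canny hysteresis thresholds for EC.
#' @return data.frame with `timestamp_s` and one column per factor
#'   (first-frame CSD is 0).
#' @export
factors_from_video <- function(frames, gaze, monitor, fps = 2, v = 3,
                               e = 1.12, block = 9L, search_range = 16L,
                               compute = c("csd", "sd", "fce", "ec"),
                               canny_low = 50, canny_high = 150) {
  if (is.character(frames)) frames <- lapply(list_frames(frames, "ppm"), read_ppm)
  n <- length(frames)
  fs_assert(nrow(gaze) >= n, "fs_grid_mismatch",
            "need one gaze sample per video frame")
  nr <- dim(frames[[1]])[1]; nc <- dim(frames[[1]])[2]
  scale <- nc / monitor[1]
  radius <- gaze_circle(nc, v, e)
  out <- data.frame(timestamp_s = (seq_len(n) - 1) / fps)
  for (f in compute) out[[f]] <- 0
  prev_fov <- NULL
  for (i in seq_len(n)) {
    pair <- normalize_brightness(split_anaglyph(frames[[i]]))
    gx_frame <- min(nc, max(1, gaze$screen_x[i] * scale + 1))
    gy_frame <- min(nr, max(1, gaze$screen_y[i] * scale + 1))
    fp <- refine_foveation_point(pair$left, c(gx_frame, gy_frame), radius)
    mask <- build_mask(c(nr, nc), fp$xcf, N = nc, v = v)
    if (any(c("csd", "sd") %in% compute)) {
      disp <- compute_disparity(pair, block, search_range)
      fov <- foveate_disparity(disp, mask)
      if ("sd" %in% compute) out$sd[i] <- sum(abs(fov))
      if ("csd" %in% compute)
        out$csd[i] <- if (is.null(prev_fov)) 0 else compute_csd(prev_fov, fov)
      prev_fov <- fov
    }
    if ("fce" %in% compute)
      out$fce[i] <- compute_fce(gaze$screen_x[i], monitor[1])
    if ("ec" %in% compute)
      out$ec[i] <- compute_ec(apply_mask(pair$left, mask),
                              apply_mask(pair$right, mask),
                              canny_low, canny_high)
  }
  out
}

#' Correlate windowed blink rate with each windowed factor
#'
#' @param track data.frame from [track_eye_frames()].
#' @param factors data.frame from [factors_from_video()].
#' @param fps_eye eye-frame rate.
#' @param window,step window length and advance in seconds.
#' @return list with `windows` (the paired normalized table per factor) and
#'   `stats` (per-factor `pearson_r`, `gradient`, `r_squared`).
#' @export
session_stats <- function(track, factors, fps_eye, window = 60, step = 10) {
  dur <- min(max(track$timestamp_s) + 1 / fps_eye,
             max(factors$timestamp_s) + diff(factors$timestamp_s[1:2]))
  br <- blink_rate_series(track$state, fps_eye, window, step,
                          total_duration = dur)
  fac_names <- setdiff(names(factors), "timestamp_s")
  windows <- list(); stats <- list()
  for (f in fac_names) {
    fs <- factor_series(factors[[f]], factors$timestamp_s, window, step,
                        total_duration = dur)
    pr <- pair_and_normalize(br, fs)
    windows[[f]] <- pr
    stats[[f]] <- correlate(pr)
  }
  list(windows = windows, stats = stats, blink = br)
}

#' Generate a coupled eye + anaglyph session with known linear relation
#'
#' Blink events and disparity changes share one schedule: each 10-second
#' segment `k` of the session holds `events[k]` blinks and `events[k]`
#' disparity switches (alternating between `disp_lo` and `disp_hi`), so
#' windowed blink rate and windowed CSD are linearly coupled by
#' construction.
#'
#' @param duration_s session length in seconds.
#' @param events per-10-s-segment event counts; defaults to a linear ramp.
#' @param fps_eye,fps_video frame rates of the two streams.
#' @param disp_lo,disp_hi the two disparity plateaus (pixels).
#' @param seed integer seed.
#' @param ... passed to [eye_scene_spec()] (noise, geometry, ...).
#' @return list with `eye` (frames + truth), `video` (frames + truth),
#'   `events`.
#' @export
gen_coupled_session <- function(duration_s = 180, events = NULL,
                                fps_eye = 5, fps_video = 2,
                                disp_lo = 3, disp_hi = 6, seed = 1L, ...) {
  nseg <- floor(duration_s / 10)
  if (is.null(events)) events <- pmin(4L, 1L + (seq_len(nseg) - 1L) %/% 4L)
  fs_assert(length(events) == nseg, "fs_spec_error",
            "events must have one entry per 10-s segment")
  blink_iv <- list(); change_t <- numeric(0)
  for (k in seq_len(nseg)) {
    m <- events[k]
    if (m == 0) next
    at <- (k - 1) * 10 + (seq_len(m) - 0.5) * 10 / m
    for (a in at) blink_iv[[length(blink_iv) + 1]] <- c(a, a + 0.6)
    change_t <- c(change_t, at)
  }
  ## disparity toggles between the two plateaus at each event time
  lev <- rep(c(disp_hi, disp_lo), length.out = length(change_t))
  sched <- data.frame(t = c(0, change_t), d = c(disp_lo, lev))
  eye <- gen_eye_sequence(
    eye_scene_spec(blink_schedule = blink_iv, seed = seed, ...),
    fps = fps_eye, duration_s = duration_s)
  vid <- gen_anaglyph_video(
    stereo_scene_spec(disparity_schedule = sched, seed = seed + 1L),
    fps = fps_video, duration_s = duration_s)
  list(eye = eye, video = vid, events = events)
}
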