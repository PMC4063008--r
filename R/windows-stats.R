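## Windowing and the statistical battery: blink rate and each factor are
## accumulated in 60-second windows advanced by 10 s (50 s overlap), paired,
## min-max normalized, and related by Pearson correlation / regression,
## a 2^2 factorial design, Cohen's d and a paired two-tailed t-test.

#' Number of sliding windows covering a recording
#'
#' `floor((total - window) / step) + 1`, or 0 when the recording is shorter
#' than one window.
#'
#' @param total_duration,window,step seconds.
#' @return integer count.
#' @export
count_windows <- function(total_duration, window = 60, step = 10) {
  fs_assert(window > 0 && step > 0, "fs_degenerate_input",
            "window and step must be positive")
  if (total_duration < window) return(0L)
  as.integer(floor((total_duration - window) / step) + 1L)
}

## Window start times for a recording; windows are [t, t + window).
window_starts <- function(total_duration, window = 60, step = 10) {
  n <- count_windows(total_duration, window, step)
  if (n == 0L) return(numeric(0))
  (seq_len(n) - 1L) * step
}

#' Blink rate per window from a per-frame eye-state sequence
#'
#' A blink is a closed-to-open transition (the reopening, not the closing);
#' it is credited to every window containing both frames of the transition.
#'
#' @param states character vector, `"open"`/`"closed"` per frame.
#' @param fps frame rate (frames per second).
#' @param window,step window length and advance in seconds.
#' @param total_duration recording length in seconds; defaults to
#'   `length(states) / fps`.
#' @return data.frame with `t_start` and `blink_rate` per window.
#' @export
blink_rate_series <- function(states, fps, window = 60, step = 10,
                              total_duration = length(states) / fps) {
  n <- length(states)
  trans <- which(states[-n] == "closed" & states[-1] == "open")  # index of closed frame
  t_closed <- (trans - 1) / fps          # timestamps of the two frames
  t_open <- trans / fps
  starts <- window_starts(total_duration, window, step)
  rate <- vapply(starts, function(s)
    sum(t_closed >= s & t_open < s + window), 0)
  data.frame(t_start = starts, blink_rate = rate)
}

#' Per-window sums of a per-frame factor series
#'
#' @param values per-frame factor values.
#' @param times per-frame timestamps in seconds.
#' @param window,step window length and advance in seconds.
#' @param total_duration recording length; defaults to covering all frames.
#' @return data.frame with `t_start` and `value` (window sum).
#' @export
factor_series <- function(values, times, window = 60, step = 10,
                          total_duration = max(times) + min(diff(sort(times)))) {
  starts <- window_starts(total_duration, window, step)
  v <- vapply(starts, function(s)
    sum(values[times >= s & times < s + window], na.rm = TRUE), 0)
  data.frame(t_start = starts, value = v)
}

#' Pair two window series and min-max normalize each to [0, 1]
#'
#' A constant series maps to all zeros (declared convention).
#'
#' @param br data.frame from [blink_rate_series()].
#' @param factor data.frame from [factor_series()].
#' @return data.frame with `t_start`, `br`, `factor` (both normalized).
#' @export
pair_and_normalize <- function(br, factor) {
  fs_assert(nrow(br) == nrow(factor) &&
              isTRUE(all.equal(br$t_start, factor$t_start)),
            "fs_grid_mismatch", "window grids differ")
  data.frame(t_start = br$t_start,
             br = minmax01(br[[2]]),
             factor = minmax01(factor[[2]]))
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Correlation and regression of blink rate on a factor
#'
#' @param pairs data.frame from [pair_and_normalize()] (columns `br`,
#'   `factor`), or any data.frame whose last two columns are (y, x).
#' @return list with `pearson_r`, `gradient` (OLS slope of blink rate on the
#'   factor), and `r_squared`.
#' @export
correlate <- function(pairs) {
  y <- pairs$br; x <- pairs$factor
  fs_assert(length(x) >= 3, "fs_degenerate_input", "need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0)
    fs_error("fs_degenerate_input", "constant series: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(pearson_r = r, gradient = slope, r_squared = r^2)
}

#' Two-factor (2^2) factorial decomposition of four cell means
#'
#' With design coding `x_A, x_B` = (-1,-1), (1,-1), (-1,1), (1,1) for the
#' cells (Large,Large), (Small,Large), (Large,Small), (Small,Small) of the
#' two factors, the response model `y = q0 + qA xA + qB xB + qAB xA xB`
#' solves exactly:
#' `q0 = (y1+y2+y3+y4)/4`, `qA = (-y1+y2-y3+y4)/4`,
#' `qB = (-y1-y2+y3+y4)/4`, `qAB = (y1-y2-y3+y4)/4`;
#' the sums of squares are `SS. = 4 q.^2`, `SST = SSA + SSB + SSAB`, and
#' the effect ratios `100 SS./SST` per cent.
#'
#' @param y1,y2,y3,y4 cell-mean responses in design order.
#' @return list with `q0, qA, qB, qAB`, `SSA, SSB, SSAB, SST`,
#'   `ratioA, ratioB, ratioAB` (per cent).
#' @export
factorial_2k <- function(y1, y2, y3, y4) {
  fs_assert(all(is.finite(c(y1, y2, y3, y4))), "fs_degenerate_input",
            "cell means must be finite")
  q0 <- (y1 + y2 + y3 + y4) / 4
  qA <- (-y1 + y2 - y3 + y4) / 4
  qB <- (-y1 - y2 + y3 + y4) / 4
  qAB <- (y1 - y2 - y3 + y4) / 4
  SSA <- 4 * qA^2; SSB <- 4 * qB^2; SSAB <- 4 * qAB^2
  SST <- SSA + SSB + SSAB
  if (SST == 0)
    fs_error("fs_degenerate_design", "all effects zero: ratios undefined")
  list(q0 = q0, qA = qA, qB = qB, qAB = qAB,
       SSA = SSA, SSB = SSB, SSAB = SSAB, SST = SST,
       ratioA = 100 * SSA / SST, ratioB = 100 * SSB / SST,
       ratioAB = 100 * SSAB / SST)
}

#' Cohen's d with the n-balanced pooled standard deviation
#'
#' `d = |m1 - m2| / sqrt((s1^2 + s2^2) / 2)`, labelled by the nearest of
#' the conventional anchors 0.2 (small), 0.5 (medium), 0.8 (large); values
#' above 0.8 are large.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return list with `d` and `label`.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  fs_assert(sd1 >= 0 && sd2 >= 0, "fs_degenerate_input",
            "standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0)
    fs_error("fs_zero_spread", "both groups have zero spread")
  d <- abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
  list(d = d, label = effect_size_label(d))
}

#' Effect-size label for a Cohen's d value
#'
#' @param d Cohen's d (absolute value is used).
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_label <- function(d) {
  anchors <- c(small = 0.2, medium = 0.5, large = 0.8)
  names(anchors)[which.min(abs(anchors - abs(d)))]
}

#' Paired two-tailed t-test
#'
#' @param before,after paired score vectors of equal length >= 2.
#' @return list with `t`, `p` (two-tailed, `n - 1` df), `df`.
#' @export
paired_ttest_two_tailed <- function(before, after) {
  fs_assert(length(before) == length(after) && length(before) >= 2,
            "fs_degenerate_input", "need equal-length samples of size >= 2")
  d <- after - before
  if (all(d == 0))
    fs_error("fs_degenerate_input", "all paired differences are zero")
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), df = n - 1), df = n - 1)
}
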