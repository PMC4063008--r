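test_that("window counting matches the worked examples", {
  expect_equal(count_windows(1530, 60, 10), 148L)
  expect_equal(count_windows(80, 60, 10), 3L)
  expect_equal(count_windows(60, 60, 10), 1L)
  expect_equal(count_windows(59, 60, 10), 0L)
})

test_that("blink counting credits reopenings with both frames in-window", {
  fps <- 10
  states <- rep("open", 70 * fps)
  close_at <- function(s, t0, t1) {
    s[(t0 * fps + 1):(t1 * fps)] <- "closed"; s
  }
  ## three blinks inside the single full 60 s window of a 70 s recording
  ## is counted per window [t, t+60): blinks at 5, 20, 40 s
  st <- close_at(close_at(close_at(states, 5, 6), 20, 21), 40, 41)
  br <- blink_rate_series(st, fps, total_duration = 70)
  expect_equal(br$blink_rate[1], 3)
  expect_equal(nrow(br), count_windows(70, 60, 10))

  ## all-open sequence: zero everywhere
  expect_true(all(blink_rate_series(states, fps)$blink_rate == 0))

  ## reopening exactly at a window boundary is excluded from the earlier
  ## window (the open frame falls outside [t, t+60))
  st2 <- close_at(rep("open", 130 * fps), 59.5, 60)
  br2 <- blink_rate_series(st2, fps, total_duration = 130)
  expect_equal(br2$blink_rate[1], 0)    # window [0, 60): reopening at 60
  expect_equal(br2$blink_rate[2], 1)    # window [10, 70) holds both frames
})

test_that("synthetic blink schedules are recovered exactly per window", {
  for (seed in 1:3) {
    set.seed(seed)
    dur <- 100; fps <- 5
    n_bl <- 6
    t0 <- sort(sample(seq(2, dur - 3, by = 2), n_bl))
    iv <- lapply(t0, function(a) c(a, a + 0.6))
    spec <- eye_scene_spec(blink_schedule = iv, seed = seed)
    res <- gen_eye_sequence(spec, fps, dur)
    ## scheduled counts from the rendered truth states
    truth_br <- blink_rate_series(res$truth$state, fps, total_duration = dur)
    track <- track_eye_frames(res$frames, fps, refine = FALSE)
    got_br <- blink_rate_series(track$state, fps, total_duration = dur)
    expect_equal(got_br$blink_rate, truth_br$blink_rate)
    expect_true(any(truth_br$blink_rate > 0))
  }
})

test_that("min-max pairing normalizes per variable with the 0-convention", {
  br <- data.frame(t_start = c(0, 10, 20), blink_rate = c(0, 5, 10))
  fa <- data.frame(t_start = c(0, 10, 20), value = c(7, 7, 7))
  pr <- pair_and_normalize(br, fa)
  expect_equal(pr$br, c(0, 0.5, 1))
  expect_equal(pr$factor, c(0, 0, 0))        # constant maps to zeros
  bad <- data.frame(t_start = c(0, 10), value = c(1, 2))
  expect_condition_class(pair_and_normalize(br, bad), "fs_grid_mismatch")
})

test_that("correlation/regression agree with base R on a hand dataset", {
  x <- c(0.1, 0.3, 0.4, 0.7, 0.9)
  y <- c(0.2, 0.1, 0.5, 0.8, 0.7)
  res <- correlate(data.frame(br = y, factor = x))
  expect_equal(res$pearson_r, cor(x, y), tolerance = 1e-12)
  fit <- lm(y ~ x)
  expect_equal(res$gradient, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res$r_squared, summary(fit)$r.squared, tolerance = 1e-12)

  exact <- correlate(data.frame(br = 3 - 2 * x, factor = x))
  expect_equal(exact$pearson_r, -1, tolerance = 1e-12)
  expect_equal(exact$gradient, -2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_condition_class(
    correlate(data.frame(br = y, factor = rep(1, 5))), "fs_degenerate_input")
})

test_that("2^2 factorial solve matches the direct linear-system oracle", {
  ## oracle: invert the design matrix of the 4-cell model directly
  X <- rbind(c(1, -1, -1, 1), c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, 1, 1, 1))
  y <- c(0.4842, 0.5871, 0.4703, 0.4098)
  q_oracle <- solve(X, y)
  f <- factorial_2k(y[1], y[2], y[3], y[4])
  expect_equal(c(f$q0, f$qA, f$qB, f$qAB), unname(q_oracle), tolerance = 1e-12)
  ## reconstruction is exact
  expect_equal(as.numeric(X %*% c(f$q0, f$qA, f$qB, f$qAB)), y,
               tolerance = 1e-12)
  ## decomposition closes
  expect_equal(f$SSA + f$SSB + f$SSAB, f$SST, tolerance = 1e-12)
  expect_equal(f$ratioA + f$ratioB + f$ratioAB, 100, tolerance = 1e-9)
  expect_condition_class(factorial_2k(1, 1, 1, 1), "fs_degenerate_design")
})

test_that("factorial solve is exact on random cell means", {
  set.seed(14)
  X <- rbind(c(1, -1, -1, 1), c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, 1, 1, 1))
  for (rep in 1:10) {
    y <- runif(4)
    f <- factorial_2k(y[1], y[2], y[3], y[4])
    expect_equal(as.numeric(X %*% c(f$q0, f$qA, f$qB, f$qAB)), y,
                 tolerance = 1e-12)
  }
})

test_that("Cohen's d is symmetric and labels by nearest anchor", {
  d1 <- cohens_d(0.2841, 0.1730, -0.0299, 0.2368)
  expect_equal(d1$d, cohens_d(-0.0299, 0.2368, 0.2841, 0.1730)$d)
  expect_equal(cohens_d(0.5, 0.1, 0.5, 0.2)$d, 0)
  expect_condition_class(cohens_d(1, 0, 2, 0), "fs_zero_spread")
  expect_equal(effect_size_label(0.34), "small")
  expect_equal(effect_size_label(0.36), "medium")
  expect_equal(effect_size_label(5), "large")
})

test_that("the paired t-test matches stats::t.test", {
  set.seed(15)
  before <- rnorm(8, 3, 1); after <- before + rnorm(8, 1, 1)
  res <- paired_ttest_two_tailed(before, after)
  ref <- t.test(after, before, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  ## swapping negates t, p unchanged
  sw <- paired_ttest_two_tailed(after, before)
  expect_equal(sw$t, -res$t, tolerance = 1e-12)
  expect_equal(sw$p, res$p, tolerance = 1e-12)
  ## constructed sample with mean diff 1, sd 1: t = sqrt(5) at df 4
  d <- c(0.5, 1.5, 2, 0, 1)            # mean 1, sd 0.7906? construct exactly
  d <- 1 + (d - mean(d)) / sd(d)       # mean 1, sd 1
  res2 <- paired_ttest_two_tailed(rep(0, 5), d)
  expect_equal(res2$t, sqrt(5), tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-sqrt(5), 4), tolerance = 1e-12)
  expect_condition_class(paired_ttest_two_tailed(d, d), "fs_degenerate_input")
})
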