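test_that("anaglyph split takes green as left, red as right", {
  mk <- function(r, g, b) {
    a <- array(0, dim = c(4, 6, 3))
    a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
    a
  }
  p <- split_anaglyph(mk(255, 0, 0))
  expect_true(all(p$right == 255) && all(p$left == 0))
  p <- split_anaglyph(mk(0, 255, 0))
  expect_true(all(p$left == 255) && all(p$right == 0))
  p <- split_anaglyph(mk(128, 128, 128))
  expect_equal(p$left, p$right)
  expect_condition_class(split_anaglyph(matrix(0, 4, 6)), "fs_channel_error")
})

test_that("brightness normalization equalizes the channel means", {
  set.seed(2)
  left <- matrix(runif(120, 20, 100), 10, 12)
  pair <- normalize_brightness(list(left = left, right = left * 2))
  expect_lt(abs(mean(pair$left) - mean(pair$right)), 0.5)
  expect_lt(max(abs(pair$right - left)), 1)

  eq <- normalize_brightness(list(left = left, right = left))
  expect_equal(eq$right, left)
  zz <- list(left = matrix(0, 4, 4), right = matrix(0, 4, 4))
  expect_equal(normalize_brightness(zz), zz)
  expect_condition_class(
    normalize_brightness(list(left = matrix(1, 4, 4),
                              right = matrix(0, 4, 4))), "fs_zero_image")
})

test_that("block matching agrees with the per-pixel SAD oracle", {
  left <- texture_fixture(20, 14, seed = 4)
  right <- shift_right_view(left, 2)
  fast <- compute_disparity(list(left = left, right = right),
                            block = 3, search_range = 3, lr_check = FALSE)
  slow <- oracle_sad_disparity(left, right, 3, 3)
  expect_equal(fast, slow)
})

test_that("block matching recovers known shifts and flags flat pairs", {
  left <- texture_fixture(96, 64, seed = 6)
  for (s in c(1, 4, 8)) {
    dm <- compute_disparity(list(left = left,
                                 right = shift_right_view(left, s)))
    modal <- as.numeric(names(which.max(table(dm))))
    expect_equal(modal, s)
  }
  ## identical pair: disparity 0 wherever valid
  d0 <- compute_disparity(list(left = left, right = left))
  expect_true(all(d0[!is.na(d0)] == 0))
  ## untextured pair: tie-break documents disparity 0
  flat <- matrix(128, 32, 32)
  df <- compute_disparity(list(left = flat, right = flat))
  expect_true(all(df[!is.na(df)] == 0))
})

test_that("SD sums the foveated disparity map", {
  dm <- matrix(2, 16, 16)
  expect_equal(compute_sd(dm, unit_mask(dim(dm))), 512, tolerance = 1e-6)
  expect_equal(compute_sd(matrix(0, 16, 16), unit_mask(c(16, 16))), 0,
               tolerance = 1e-9)
  ## against an elementwise oracle on a non-trivial mask
  mask <- build_mask(c(16, 16), c(9, 9), N = 16, v = 3)
  fov <- foveastrain:::foveate_disparity(dm, mask)
  expect_equal(compute_sd(dm, mask), sum(abs(fov)))
  ## invalid pixels contribute nothing
  dm_na <- dm; dm_na[1:8, ] <- NA
  dm_zero <- dm; dm_zero[1:8, ] <- 0
  expect_equal(compute_sd(dm_na, unit_mask(dim(dm))),
               compute_sd(dm_zero, unit_mask(dim(dm))), tolerance = 1e-9)
})

test_that("CSD is the elementwise absolute difference sum", {
  a <- matrix(5, 10, 10)
  expect_equal(compute_csd(a, a), 0)
  expect_equal(compute_csd(a, a + 1), 100)
  set.seed(8)
  x <- matrix(runif(100), 10, 10); y <- matrix(runif(100), 10, 10)
  expect_equal(compute_csd(x, y), sum(abs(y - x)))
  expect_condition_class(compute_csd(a, matrix(0, 5, 5)), "fs_shape_error")
})

test_that("CSD satisfies the triangle inequality", {
  set.seed(10)
  for (rep in 1:5) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    c <- matrix(runif(64), 8, 8)
    expect_lte(compute_csd(a, c),
               compute_csd(a, b) + compute_csd(b, c) + 1e-12)
  }
})

test_that("FCE reproduces the worked examples and is symmetric", {
  expect_equal(compute_fce(20, 1280), 620)
  expect_equal(compute_fce(1270, 1280), 630)
  expect_equal(compute_fce(640, 1280), 0)
  for (x in c(0, 100, 333, 640))
    expect_equal(compute_fce(x, 1280), compute_fce(1280 - x, 1280))
})

test_that("EC sums Canny magnitudes of both images symmetrically", {
  const <- matrix(80, 48, 48)
  expect_equal(compute_ec(const, const), 0)

  ## single ideal step edge: EC equals the one-sided sum
  step <- cbind(matrix(0, 48, 24), matrix(200, 48, 24))
  one <- foveastrain:::canny_magnitude_sum(step, 50, 150)
  expect_gt(one, 0)
  expect_equal(compute_ec(step, const), one)
  expect_equal(compute_ec(step, const), compute_ec(const, step))
})

test_that("Canny marks a clean step edge as a thin vertical line", {
  step <- cbind(matrix(0, 32, 16), matrix(200, 32, 16))
  ce <- canny_edges(step, 50, 150)
  cols_hit <- unique(which(ce$edges, arr.ind = TRUE)[, 2])
  expect_true(all(cols_hit %in% 15:18))       # near the transition
  expect_gt(sum(ce$edges), 0)
  ## no edges on a flat image
  expect_equal(sum(canny_edges(matrix(7, 32, 32), 50, 150)$edges), 0)
})

test_that("factor values ignore a constant brightness offset", {
  left <- texture_fixture(48, 32, seed = 12) * 0.5 + 40   # keep clip head-room
  right <- shift_right_view(left, 3)
  base <- normalize_brightness(list(left = left, right = right))
  off <- normalize_brightness(list(left = left + 20, right = right + 20))
  d1 <- compute_disparity(base, block = 5, search_range = 5)
  d2 <- compute_disparity(off, block = 5, search_range = 5)
  ## modal disparity unchanged by the common offset
  expect_equal(as.numeric(names(which.max(table(d1)))),
               as.numeric(names(which.max(table(d2)))))
})
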