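test_that("CED finds a dark pupil disk, also with a specular dot inside", {
  img <- disk_frame(200, 200, c(100, 100), 30)
  p <- detect_pupil_ced(img, 8, 60)
  expect_lt(max(abs(p$center - c(100, 100))), 2 + 1e-9)
  expect_lt(abs(p$radius - 30), 2 + 1e-9)
  expect_false(p$refined)

  ## a 5-px bright SR dot inside the pupil barely moves the optimum
  img2 <- img
  img2[95:99, 105:109] <- 255
  p2 <- detect_pupil_ced(img2, 8, 60)
  expect_lt(max(abs(p2$center - c(100, 100))), 2 + 1e-9)
})

test_that("CED reports no pupil on a contrast-free frame", {
  expect_condition_class(
    detect_pupil_ced(matrix(128, 100, 100), 8, 40), "fs_no_pupil")
})

test_that("CED agrees with the exhaustive brute-force oracle", {
  cases <- list(
    list(w = 96, h = 80, c = c(40, 38), r = 14),
    list(w = 128, h = 128, c = c(70, 55), r = 22),
    list(w = 120, h = 90, c = c(62, 47), r = 17))
  for (cs in cases) {
    img <- disk_frame(cs$w, cs$h, cs$c, cs$r)
    set.seed(cs$r)
    img <- img + matrix(round(rnorm(cs$w * cs$h, 0, 3)), cs$h, cs$w)
    fast <- foveastrain:::cpp_ced_search(img, 8L, 26L, 2L,
                                         0L, 0L, cs$w - 1L, cs$h - 1L)
    slow <- oracle_ced(img, 8, 26, 2)
    same_argmax <- fast$x == slow$x && fast$y == slow$y && fast$r == slow$r
    expect_true(same_argmax || abs(fast$score - slow$score) < 1e-9)
    expect_equal(fast$score, slow$score, tolerance = 1e-12)
  }
})

test_that("refinement recovers the disk centroid and fills SR holes", {
  img <- disk_frame(160, 140, c(80, 70), 25)
  init <- detect_pupil_ced(img, 10, 40)
  ref <- refine_pupil(img, init)
  expect_true(ref$refined)
  expect_lt(max(abs(ref$center - c(80, 70))), 0.5)

  ## punch a bright hole: the closing must restore the centroid
  hole <- img
  hole[62:68, 86:92] <- 255
  init2 <- detect_pupil_ced(hole, 10, 40)
  ref2 <- refine_pupil(hole, init2)
  expect_lt(max(abs(ref2$center - c(80, 70))), 1)
})

test_that("refinement fails cleanly when no pupil-sized component survives", {
  img <- matrix(200, 100, 100)
  img[50, 48:50] <- 10                       # 3 dark pixels only
  fake <- structure(list(center = c(50, 50), radius = 10, score = 50,
                         black_pixel_count = 3, refined = FALSE),
                    class = "pupil_result")
  expect_condition_class(refine_pupil(img, fake), "fs_refinement_failed")
})

test_that("refinement is idempotent to half a pixel", {
  for (seed in 1:3) {
    set.seed(seed)
    ctr <- c(60 + seed * 3, 55 - seed * 2)
    img <- disk_frame(130, 120, ctr, 18) +
      matrix(round(rnorm(130 * 120, 0, 2)), 120, 130)
    r1 <- refine_pupil(img, detect_pupil_ced(img, 8, 30))
    r2 <- refine_pupil(img, r1)
    expect_lt(sqrt(sum((r2$center - r1$center)^2)), 0.5)
  }
})

test_that("four specular reflections are found and ordered TL,TR,BR,BL", {
  img <- disk_frame(200, 200, c(100, 100), 20)
  dots <- rbind(c(60, 60), c(140, 60), c(140, 140), c(60, 140))
  for (k in sample(1:4)) {
    x <- dots[k, 1]; y <- dots[k, 2]
    img[(y - 1):(y + 1), (x - 1):(x + 1)] <- 255
  }
  pup <- detect_pupil_ced(img, 10, 40)
  quad <- detect_srs(img, pup)
  expect_equal(rownames(quad), c("TL", "TR", "BR", "BL"))
  expect_equal(unname(quad[, 1]), c(60, 140, 140, 60), tolerance = 1e-9)
  expect_equal(unname(quad[, 2]), c(60, 60, 140, 140), tolerance = 1e-9)

  ## an asymmetric (sheared) layout still orders correctly
  img2 <- disk_frame(200, 200, c(100, 100), 20)
  dots2 <- rbind(c(70, 55), c(150, 65), c(140, 150), c(55, 135))
  for (k in 1:4) {
    x <- dots2[k, 1]; y <- dots2[k, 2]
    img2[(y - 1):(y + 1), (x - 1):(x + 1)] <- 255
  }
  quad2 <- detect_srs(img2, detect_pupil_ced(img2, 10, 40))
  expect_equal(unname(quad2[, 1]), dots2[, 1], tolerance = 1e-9)
})

test_that("SR count errors and size filtering behave as specified", {
  base <- disk_frame(200, 200, c(100, 100), 20)
  put <- function(img, x, y, half = 1) {
    img[(y - half):(y + half), (x - half):(x + half)] <- 255
    img
  }
  three <- put(put(put(base, 60, 60), 140, 60), 140, 140)
  pup <- detect_pupil_ced(three, 10, 40)
  expect_condition_class(detect_srs(three, pup), "fs_sr_count")

  ## a fifth, 1-px dot is removed by the size band [4, 100]
  five <- put(put(put(put(base, 60, 60), 140, 60), 140, 140), 60, 140)
  five[100, 30] <- 255
  quad <- detect_srs(five, pup, size_band = c(4, 100))
  expect_equal(unname(quad[, 1]), c(60, 140, 140, 60), tolerance = 1e-9)
})

test_that("blink state follows the dark-pixel count with open ties", {
  expect_equal(blink_state(matrix(255, 50, 50), 500)$state, "closed")
  expect_equal(blink_state(matrix(255, 50, 50), 500)$black_pixel_count, 0)

  disk <- disk_frame(100, 100, c(50, 50), 30, fg = 10, bg = 255)
  n_dark <- sum(disk < 70)
  expect_gt(n_dark, 2500)                     # ~ pi * 30^2
  expect_equal(blink_state(disk, 500)$state, "open")
  ## count exactly at threshold reads open
  expect_equal(blink_state(disk, n_dark)$state, "open")
  expect_equal(blink_state(disk, n_dark + 1)$state, "closed")
})

test_that("adding dark pixels never flips the state open -> closed", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(runif(400, 0, 255), 20, 20)
    s1 <- blink_state(img, 30)
    img2 <- img
    img2[sample(400, 25)] <- 0
    s2 <- blink_state(img2, 30)
    expect_gte(s2$black_pixel_count, s1$black_pixel_count)
    if (s1$state == "open") expect_equal(s2$state, "open")
  }
})
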