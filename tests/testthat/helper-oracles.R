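## Fixture builders and independent brute-force oracles. The oracles mirror
## the *definitions* (ring score, SAD cost, TMSM) in plain vectorized R and
## never call the package's fast paths.

## Frame with a dark disk on a bright background (sharp edge, no AA).
disk_frame <- function(width, height, center, radius, fg = 20, bg = 200) {
  d <- sqrt(outer((seq_len(height) - center[2])^2,
                  (seq_len(width) - center[1])^2, `+`))
  img <- matrix(bg, height, width)
  img[d <= radius] <- fg
  img
}

## Ring mean exactly as defined: the integer annulus with
## (r-0.5)^2 <= dx^2 + dy^2 < (r+0.5)^2, off-image samples dropped.
## 0-based center; exact integer arithmetic, so bit-identical to the fast
## path by construction of the definition, not of the code.
oracle_ring_mean <- function(img, cx, cy, r) {
  off <- expand.grid(dx = (-r - 1):(r + 1), dy = (-r - 1):(r + 1))
  d2 <- off$dx^2 + off$dy^2
  off <- off[d2 >= (r - 0.5)^2 & d2 < (r + 0.5)^2, ]
  px <- cx + off$dx
  py <- cy + off$dy
  ok <- px >= 0 & px < ncol(img) & py >= 0 & py < nrow(img)
  mean(img[cbind(py[ok] + 1, px[ok] + 1)])
}

## Exhaustive CED over the full center grid / radius band; returns the
## 0-based argmax with ties resolved toward smaller r, then (y, x).
oracle_ced <- function(img, rmin, rmax, grid_step = 2) {
  annulus <- function(r) {
    off <- expand.grid(dx = (-r - 1):(r + 1), dy = (-r - 1):(r + 1))
    d2 <- off$dx^2 + off$dy^2
    off[d2 >= (r - 0.5)^2 & d2 < (r + 0.5)^2, ]
  }
  best <- list(score = -Inf)
  for (r in rmin:rmax) {
    oin <- annulus(r); oout <- annulus(r + 2)
    ## centers keep the outer annulus fully inside: no bounds handling
    xs <- seq(r + 2, ncol(img) - 1 - (r + 2), by = grid_step)
    ys <- seq(r + 2, nrow(img) - 1 - (r + 2), by = grid_step)
    for (cy in ys) for (cx in xs) {
      sc <- mean(img[cbind(cy + oout$dy + 1, cx + oout$dx + 1)]) -
        mean(img[cbind(cy + oin$dy + 1, cx + oin$dx + 1)])
      if (sc > best$score + 1e-12)
        best <- list(x = cx, y = cy, r = r, score = sc)
    }
  }
  best
}

## Direct per-pixel TMSM with replicate padding (nested loops, no conv).
oracle_tmsm_at <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  nb <- matrix(0, 3, 3)
  for (i in -1:1) for (j in -1:1)
    nb[i + 2, j + 2] <- img[min(nr, max(1, y + i)), min(nc, max(1, x + j))]
  s0 <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  s45 <- matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, 3, byrow = TRUE)
  s135 <- matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3, byrow = TRUE)
  abs(sum(s0 * nb)) + abs(sum(t(s0) * nb)) + abs(sum(s45 * nb)) +
    abs(sum(s135 * nb))
}

## Exhaustive foveation-point refinement inside the strict circle.
oracle_refine_point <- function(img, xf, radius) {
  best <- list(val = -Inf, d = Inf, x = xf[1], y = xf[2])
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    d <- sqrt((x - xf[1])^2 + (y - xf[2])^2)
    if (d >= radius) next
    v <- oracle_tmsm_at(img, x, y)
    if (v > best$val + 1e-9 ||
        (abs(v - best$val) <= 1e-9 &&
         (d < best$d - 1e-9 ||
          (abs(d - best$d) <= 1e-9 &&
           (y < best$y || (y == best$y && x < best$x))))))
      best <- list(val = v, d = d, x = x, y = y)
  }
  if (!is.finite(best$val)) best <- list(val = NA, d = 0, x = xf[1], y = xf[2])
  best
}

## Per-pixel exhaustive SAD disparity (no consistency check), same cost and
## tie rule (|d| then sign) as the matcher.
oracle_sad_disparity <- function(left, right, block, range) {
  h <- block %/% 2
  nr <- nrow(left); nc <- ncol(left)
  out <- matrix(NA_real_, nr, nc)
  cand <- c(0, as.vector(rbind(-(1:range), 1:range)))
  for (r in (h + 1):(nr - h)) for (c in (h + 1):(nc - h)) {
    bestCost <- Inf; bestD <- NA
    for (d in cand) {
      cc <- c - d
      if (cc - h < 1 || cc + h > nc) next
      cost <- sum(abs(left[(r - h):(r + h), (c - h):(c + h)] -
                      right[(r - h):(r + h), (cc - h):(cc + h)]))
      if (cost < bestCost - 1e-9) { bestCost <- cost; bestD <- d }
    }
    out[r, c] <- bestD
  }
  out
}

## Band-limited random texture in [0, 255] for matchable stereo fixtures.
texture_fixture <- function(width, height, seed = 1) {
  set.seed(seed)
  img <- matrix(runif(width * height), height, width)
  k <- matrix(1, 3, 3) / 9
  img <- conv2_replicate(img, k)
  r <- range(img)
  (img - r[1]) / (r[2] - r[1]) * 255
}

## Right view with content shifted by integer disparity d (replicate edge):
## right[, c] = left[, c + d].
shift_right_view <- function(left, d) {
  nc <- ncol(left)
  left[, pmin(nc, pmax(1, seq_len(nc) + d)), drop = FALSE]
}

expect_condition_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
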