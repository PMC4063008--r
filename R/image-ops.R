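## Small image-processing primitives shared by the detection stages.

#' 2-D convolution with replicate border handling
#'
#' Correlation form (the kernel is applied as given, not flipped), matching
#' the usual definition of Sobel-style derivative masks.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return matrix of the same shape as `img`.
#' @export
conv2_replicate <- function(img, kernel) {
  cpp_conv2_replicate(img, kernel)
}

## The four directional 3x3 Sobel masks (0, 45, 90, 135 degrees).
sobel_kernels <- function() {
  s0 <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)  # d/dx
  s90 <- t(s0)                                                       # d/dy
  s45 <- matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, 3, byrow = TRUE)
  s135 <- matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3, byrow = TRUE)
  list(s0, s45, s90, s135)
}

gaussian_kernel <- function(size = 5L, sigma = 1.4) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Otsu's threshold for an 8-bit sample of gray values
#'
#' @param values numeric vector of gray levels in `[0, 255]`.
#' @return threshold t; foreground/background split is `values < t` vs `>= t`.
#' @export
otsu_threshold <- function(values) {
  v <- as.integer(round(pmin(pmax(values, 0), 255)))
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))   # double: avoid overflow
  n <- sum(h)
  fs_assert(n > 0, "fs_degenerate_input", "empty sample for Otsu threshold")
  levels <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * levels)
  mt <- m0[256]
  w1 <- n - w0
  between <- rep(0, 256)
  ok <- w0 > 0 & w1 > 0
  between[ok] <- (mt * w0[ok] / n - m0[ok])^2 / (w0[ok] * w1[ok]) * n
  levels[which.max(between)] + 0.5
}

#' Label 8-connected components of a logical mask
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  cpp_label_components(mask)
}

## Per-component area and centroid (x, y), 1-based pixel coordinates.
component_stats <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(id = integer(), area = integer(),
                      cx = numeric(), cy = numeric()))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- as.integer(tapply(lab, lab, length))
  cy <- as.numeric(tapply(idx[, 1], lab, mean))
  cx <- as.numeric(tapply(idx[, 2], lab, mean))
  data.frame(id = ids, area = area, cx = cx, cy = cy)
}

## 3x3 binary dilation / erosion via shifted maxima/minima.
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    out <- out | shift_mat(mask, dr, dc, FALSE)
  out
}

erode3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    out <- out & shift_mat(mask, dr, dc, TRUE)
  out
}

#' Morphological closing (dilate then erode) with a 3x3 structuring element
#'
#' @param mask logical matrix.
#' @param iterations number of dilation passes before the matching erosions;
#'   closing with k iterations fills holes up to roughly `2k` pixels across.
#' @return logical matrix.
#' @export
close_mask <- function(mask, iterations = 2L) {
  m <- mask
  for (i in seq_len(iterations)) m <- dilate3(m)
  for (i in seq_len(iterations)) m <- erode3(m)
  m
}

## NB: x first so pmin/pmax keep its dim attributes.
clip01 <- function(x) pmin(pmax(x, 0), 1)

clip_range <- function(x, range) pmin(pmax(x, range[1]), range[2])
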