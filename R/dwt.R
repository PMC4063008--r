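## Separable 2-D orthogonal discrete wavelet transform on the Daubechies
## bases, periodized (circular) so the decomposition is non-redundant and
## reconstruction is exact to machine precision. No wavelet library ships
## with the supported toolchain, so the filter bank lives here.

## Orthonormal lowpass filters; highpass by the quadrature-mirror relation
## g[k] = (-1)^k h[L-1-k].
daubechies_filter <- function(wavelet = c("db4", "db2")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, L = L)
}

## One periodized analysis step on the columns of x (treating each column as
## a signal); returns approximation and detail halves.
dwt_step_cols <- function(x, filt) {
  n <- nrow(x)
  n2 <- n %/% 2L
  idx0 <- 2L * (seq_len(n2) - 1L)
  a <- matrix(0, n2, ncol(x)); d <- a
  for (k in seq_len(filt$L)) {
    rows <- ((idx0 + (k - 1L)) %% n) + 1L
    a <- a + filt$h[k] * x[rows, , drop = FALSE]
    d <- d + filt$g[k] * x[rows, , drop = FALSE]
  }
  list(a = a, d = d)
}

idwt_step_cols <- function(a, d, filt) {
  n2 <- nrow(a); n <- 2L * n2
  x <- matrix(0, n, ncol(a))
  idx0 <- 2L * (seq_len(n2) - 1L)
  for (k in seq_len(filt$L)) {
    rows <- ((idx0 + (k - 1L)) %% n) + 1L
    x[rows, ] <- x[rows, , drop = FALSE] +
      filt$h[k] * a + filt$g[k] * d
  }
  x
}

#' Multi-level 2-D discrete wavelet transform
#'
#' @param img numeric matrix; both dimensions must be divisible by
#'   `2^levels` (see [pad_for_dwt()]).
#' @param levels number of decomposition levels.
#' @param wavelet `"db4"` (default) or `"db2"`.
#' @return a `dwt2` list: `LL` (deepest approximation) and `detail[[lev]]`
#'   with matrices `LH`, `HL`, `HH`; `HL` is high-frequency in x
#'   (columns), `LH` high-frequency in y (rows).
#' @export
dwt2 <- function(img, levels = 4L, wavelet = "db4") {
  filt <- daubechies_filter(wavelet)
  fs_assert(nrow(img) %% 2^levels == 0 && ncol(img) %% 2^levels == 0,
            "fs_shape_error",
            sprintf("image %dx%d not divisible by 2^%d; pad first",
                    nrow(img), ncol(img), levels))
  detail <- vector("list", levels)
  cur <- img
  for (lev in seq_len(levels)) {
    cstep <- dwt_step_cols(cur, filt)                # filter along y first
    ## naming: first letter = x (column) band, second = y (row) band
    rowlow <- cstep$a; rowhigh <- cstep$d
    colsplit_low <- dwt_step_cols(t(rowlow), filt)
    colsplit_high <- dwt_step_cols(t(rowhigh), filt)
    detail[[lev]] <- list(HL = t(colsplit_low$d),    # high x, low y
                          LH = t(colsplit_high$a),   # low x, high y
                          HH = t(colsplit_high$d))
    cur <- t(colsplit_low$a)
  }
  structure(list(LL = cur, detail = detail, levels = levels,
                 wavelet = wavelet, dim = dim(img)),
            class = "dwt2")
}

#' Inverse multi-level 2-D discrete wavelet transform
#'
#' @param w a `dwt2` object.
#' @return reconstructed matrix of the original shape.
#' @export
idwt2 <- function(w) {
  filt <- daubechies_filter(w$wavelet)
  cur <- w$LL
  for (lev in rev(seq_len(w$levels))) {
    d <- w$detail[[lev]]
    rowlow <- t(idwt_step_cols(t(cur), t_or(d$HL), filt))
    rowhigh <- t(idwt_step_cols(t_or(d$LH), t_or(d$HH), filt))
    cur <- idwt_step_cols(rowlow, rowhigh, filt)
  }
  cur
}

t_or <- function(m) t(m)

#' Pad an image symmetrically so its dimensions divide `2^levels`
#'
#' @param img numeric matrix.
#' @param levels decomposition depth the padded image must support.
#' @return list `img` (padded, reflection at bottom/right), `nr`, `nc`
#'   (original shape).
#' @export
pad_for_dwt <- function(img, levels = 4L) {
  blk <- 2L^levels
  nr <- nrow(img); nc <- ncol(img)
  pr <- (blk - nr %% blk) %% blk
  pc <- (blk - nc %% blk) %% blk
  if (pr > nr || pc > nc)
    fs_error("fs_shape_error",
             sprintf("image %dx%d too small to pad for %d levels", nr, nc, levels))
  out <- img
  if (pr > 0) out <- rbind(out, out[nr:(nr - pr + 1L), , drop = FALSE])
  if (pc > 0) out <- cbind(out, out[, nc:(nc - pc + 1L), drop = FALSE])
  list(img = out, nr = nr, nc = nc)
}
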