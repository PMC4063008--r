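## Images are plain numeric matrices in [0, 255], indexed [row, col]
## (y down, x right); positions in the API are (x, y) pairs, 1-based.
## RGB frames are nr x nc x 3 arrays in the same range.
##
## Frames travel as portable anymap files (PGM for gray, PPM for color),
## both the text (P2/P3) and binary (P5/P6) variants, so sequences can be
## stored and inspected with no external imaging library.

#' Read a PGM (P2/P5) image as a numeric matrix
#'
#' @param path file path.
#' @return numeric matrix with values in `[0, maxval]`, `[row, col]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- pnm_token(con)
  fs_assert(magic %in% c("P2", "P5"), "fs_io_error",
            sprintf("not a PGM file (magic '%s')", magic))
  nc <- as.integer(pnm_token(con))
  nr <- as.integer(pnm_token(con))
  maxv <- as.integer(pnm_token(con))
  n <- nr * nc
  vals <- if (magic == "P5") {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    scan(con, what = double(), n = n, quiet = TRUE, comment.char = "#")
  }
  fs_assert(length(vals) == n, "fs_io_error", "truncated PGM payload")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a numeric matrix as a PGM image
#'
#' @param img numeric matrix, values clipped and rounded to `[0, 255]`.
#' @param path output path.
#' @param ascii write the text P2 variant instead of binary P5.
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  v <- as.integer(round(pmin(255, pmax(0, t(img)))))
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    writeLines(paste(v, collapse = "\n"), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
    writeBin(v, con, size = 1L)
  }
  invisible(path)
}

#' Read a PPM (P3/P6) image as an RGB array
#'
#' @param path file path.
#' @return numeric array `nr x nc x 3` with values in `[0, maxval]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- pnm_token(con)
  fs_assert(magic %in% c("P3", "P6"), "fs_io_error",
            sprintf("not a PPM file (magic '%s')", magic))
  nc <- as.integer(pnm_token(con))
  nr <- as.integer(pnm_token(con))
  maxv <- as.integer(pnm_token(con))
  n <- nr * nc * 3L
  vals <- if (magic == "P6") {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    scan(con, what = double(), n = n, quiet = TRUE, comment.char = "#")
  }
  fs_assert(length(vals) == n, "fs_io_error", "truncated PPM payload")
  ## interleaved RGB, row-major
  m <- matrix(vals, nrow = 3L)
  out <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(m[ch, ], nrow = nr, byrow = TRUE)
  out
}

#' Write an RGB array as a PPM image
#'
#' @param img numeric array `nr x nc x 3`.
#' @param path output path.
#' @param ascii write the text P3 variant instead of binary P6.
#' @export
write_ppm <- function(img, path, ascii = FALSE) {
  fs_assert(length(dim(img)) == 3 && dim(img)[3] == 3, "fs_channel_error",
            "expected an nr x nc x 3 array")
  nr <- dim(img)[1]; nc <- dim(img)[2]
  m <- rbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
             as.vector(t(img[, , 3])))
  v <- as.integer(round(pmin(255, pmax(0, as.vector(m)))))
  con <- file(path, "wb")
  on.exit(close(con))
  if (ascii) {
    writeLines(c("P3", paste(nc, nr), "255"), con)
    writeLines(paste(v, collapse = "\n"), con)
  } else {
    writeLines(c("P6", paste(nc, nr), "255"), con)
    writeBin(v, con, size = 1L)
  }
  invisible(path)
}

## Whitespace/comment-aware token reader for PNM headers.
pnm_token <- function(con) {
  tok <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0 || ch == "") {
      if (nzchar(tok)) return(tok)
      fs_error("fs_io_error", "unexpected end of PNM header")
    }
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "" || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) return(tok)
    } else {
      tok <- paste0(tok, ch)
    }
  }
}

#' List the frame files of a numbered image directory in frame order
#'
#' @param dir directory containing `*.pgm`/`*.ppm` frames with zero-padded
#'   numeric stems (as written by the generators).
#' @param ext file extension, `"pgm"` or `"ppm"`.
#' @return character vector of paths, sorted by the numeric part of the stem.
#' @export
list_frames <- function(dir, ext = "pgm") {
  fls <- list.files(dir, pattern = paste0("\\.", ext, "$"), full.names = TRUE)
  fs_assert(length(fls) > 0, "fs_io_error",
            sprintf("no .%s frames found in %s", ext, dir))
  num <- as.integer(gsub("\\D", "", basename(fls)))
  fls[order(num)]
}
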