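#' @importFrom stats rnorm runif fft sd setNames predict
#' @importFrom utils write.csv read.csv
NULL

#' Validate an RGB image array
#'
#' An RGB image is a plain `H x W x 3` numeric array with channel values on
#' the 8-bit scale `[0, 255]`. Matrix element `[i, j, c]` is row `i`
#' (top to bottom), column `j` (left to right), channel `c` in R, G, B order.
#'
#' @param img object to validate.
#' @param what name used in error messages.
#' @return the image, invisibly, after validation.
#' @keywords internal
assert_rgb <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 16L || dim(img)[2] < 16L)
    stop(what, " must be at least 16 x 16 pixels", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " channel values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

assert_gray <- function(img, what = "img") {
  if (!is.matrix(img))
    stop(what, " must be a 2-D matrix", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Read an image file as an RGB array
#'
#' Reads JPEG/PNG/TIFF via EBImage and returns an `H x W x 3` array on the
#' `[0, 255]` scale. Grayscale files are replicated across the three
#' channels; an alpha channel, if present, is dropped. 16-bit inputs are
#' rescaled to `[0, 255]` on load.
#'
#' @param path path to a JPEG, PNG or TIFF file.
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  px <- EBImage::imageData(im)
  if (length(d) == 2L) {
    arr <- array(rep(t(px), 3L), dim = c(d[2], d[1], 3L))
  } else {
    if (d[3] > 3L) px <- px[, , 1:3, drop = FALSE]
    if (d[3] < 3L) px <- array(rep(px[, , 1L], 3L), dim = c(d[1], d[2], 3L))
    arr <- aperm(px, c(2L, 1L, 3L))
  }
  if (max(arr) > 1) arr <- arr / max(arr)  # defensive: EBImage scales to [0,1]
  arr * 255
}

#' Write an RGB array to an image file
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param path output path; format taken from the extension (png/jpeg/tiff).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  assert_rgb(img)
  im <- EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(im, path)
  invisible(path)
}

# replicate-pad a matrix by hy rows on top/bottom and hx columns left/right
pad_replicate <- function(m, hy, hx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, hy), seq_len(nr), rep(nr, hy))
  ci <- c(rep(1L, hx), seq_len(nc), rep(nc, hx))
  m[ri, ci, drop = FALSE]
}

# exact spatial cross-correlation with replicate padding, 'same' output.
# Used for small kernels (Sobel); shift-and-add keeps integer inputs exact.
correlate2_shift <- function(m, k) {
  hy <- (nrow(k) - 1L) %/% 2L
  hx <- (ncol(k) - 1L) %/% 2L
  p <- pad_replicate(m, hy, hx)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dy in seq_len(nrow(k))) {
    for (dx in seq_len(ncol(k))) {
      w <- k[dy, dx]
      if (w != 0)
        out <- out + w * p[dy:(dy + nr - 1L), dx:(dx + nc - 1L), drop = FALSE]
    }
  }
  out
}

# FFT-based cross-correlation with replicate padding, 'same' output.
# Handles kernels larger than the image (padding grows the canvas enough).
correlate2_fft <- function(m, k) {
  hy <- (nrow(k) - 1L) %/% 2L
  hx <- (ncol(k) - 1L) %/% 2L
  p <- pad_replicate(m, hy, hx)
  # correlation = convolution with the 180-degree rotated kernel
  kr <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  fr <- nrow(p) + nrow(k) - 1L
  fc <- ncol(p) + ncol(k) - 1L
  P <- matrix(0, fr, fc); P[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  K <- matrix(0, fr, fc); K[seq_len(nrow(k)), seq_len(ncol(k))] <- kr
  full <- Re(fft(fft(P) * fft(K), inverse = TRUE)) / (fr * fc)
  r0 <- nrow(k)  # first 'valid' row of the full correlation over the padded image
  c0 <- ncol(k)
  full[r0:(r0 + nrow(m) - 1L), c0:(c0 + ncol(m) - 1L), drop = FALSE]
}
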