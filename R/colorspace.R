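#' Convert an RGB image to the HSI color space
#'
#' Hue-saturation-intensity transform. For each pixel,
#' \deqn{\theta = \arccos\frac{0.5[(R-G)+(R-B)]}
#'                            {\sqrt{(R-G)^2+(R-B)(G-B)}},}
#' with hue \eqn{H = \theta} when \eqn{G \ge B} and \eqn{H = 2\pi - \theta}
#' otherwise; saturation \eqn{S = 1 - 3\min(R,G,B)/(R+G+B)}; intensity
#' \eqn{I = (R+G+B)/3}. HSI separates chromatic content from brightness,
#' which damps illumination differences between photographs.
#'
#' Degenerate pixels get defined fallbacks rather than NaN: black pixels
#' (`R+G+B = 0`) map to `H = 0, S = 0, I = 0` so that an exactly black
#' background stays constant; gray pixels (`R = G = B > 0`) have undefined
#' hue and map to `H = 0`. The arccos argument is clamped to `[-1, 1]` to
#' absorb floating-point overshoot.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @return list of three `H x W` matrices: `h` (hue, radians in
#'   `[0, 2*pi)`), `s` (saturation in `[0, 1]`), `i` (intensity in
#'   `[0, 255]`).
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))  # pure red
#' # rgb_to_hsi needs >= 16x16; inspect via a filled canvas
#' img <- array(rep(c(255, 0, 0), each = 256), dim = c(16, 16, 3))
#' hsi <- rgb_to_hsi(img)
#' c(h = hsi$h[1, 1], s = hsi$s[1, 1], i = hsi$i[1, 1])
#' @export
rgb_to_hsi <- function(img) {
  assert_rgb(img)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  total <- R + G + B
  i <- total / 3

  s <- matrix(0, nrow(R), ncol(R))
  nonblack <- total > 0
  s[nonblack] <- 1 - 3 * pmin(R, G, B)[nonblack] / total[nonblack]

  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  h <- matrix(0, nrow(R), ncol(R))
  chroma <- den > 0
  arg <- pmin(1, pmax(-1, num[chroma] / den[chroma]))
  theta <- acos(arg)
  flip <- (G < B)[chroma]
  theta[flip] <- 2 * pi - theta[flip]
  theta[theta >= 2 * pi] <- 0
  h[chroma] <- theta

  list(h = h, s = s, i = i)
}
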