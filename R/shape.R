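#' Raw image moment
#'
#' \eqn{m_{pq} = \sum_x \sum_y x^p y^q I(x, y)} with 1-based indices,
#' `x` running over rows and `y` over columns.
#'
#' @param img grayscale matrix, not all zero.
#' @param p,q non-negative integer orders.
#' @return the moment, a scalar.
#' @export
raw_moment <- function(img, p, q) {
  if (!is.matrix(img)) stop("img must be a 2-D matrix", call. = FALSE)
  stopifnot(p >= 0, q >= 0)
  if (all(img == 0)) stop("empty image", call. = FALSE)
  x <- seq_len(nrow(img)); y <- seq_len(ncol(img))
  sum((x^p) * (img %*% (y^q)))
}

#' Central image moment
#'
#' \eqn{\mu_{pq} = \sum_x \sum_y (x - \bar x)^p (y - \bar y)^q I(x, y)}
#' about the intensity centroid \eqn{\bar x = m_{10}/m_{00}},
#' \eqn{\bar y = m_{01}/m_{00}}. Translation-invariant by construction;
#' \eqn{\mu_{10} = \mu_{01} = 0} identically.
#'
#' @inheritParams raw_moment
#' @return the central moment, a scalar.
#' @export
central_moment <- function(img, p, q) {
  if (!is.matrix(img)) stop("img must be a 2-D matrix", call. = FALSE)
  m00 <- raw_moment(img, 0, 0)
  xbar <- raw_moment(img, 1, 0) / m00
  ybar <- raw_moment(img, 0, 1) / m00
  x <- seq_len(nrow(img)) - xbar
  y <- seq_len(ncol(img)) - ybar
  sum((x^p) * (img %*% (y^q)))
}

#' Normalized central moment
#'
#' \eqn{e_{pq} = \mu_{pq} / \mu_{00}^{(p+q+2)/2}}, which removes the
#' dependence on spatial scale for `p + q >= 2`.
#'
#' @inheritParams raw_moment
#' @return the normalized moment, a scalar.
#' @export
normalized_moment <- function(img, p, q) {
  stopifnot(p + q >= 2)
  mu00 <- central_moment(img, 0, 0)
  if (mu00 == 0) stop("empty image", call. = FALSE)
  central_moment(img, p, q) / mu00^((p + q + 2) / 2)
}

#' The seven Hu invariant moments
#'
#' Algebraic combinations of the normalized central moments up to order 3
#' that are invariant to translation, rotation and spatial scale; the
#' seventh is a skew invariant that flips sign under mirroring. Values are
#' returned raw (no log transform): they are the shape feature itself, not
#' a display quantity.
#'
#' @param img grayscale matrix with positive total mass.
#' @return named numeric vector `h1` .. `h7`.
#' @examples
#' img <- matrix(0, 32, 32); img[9:24, 13:20] <- 1
#' hu_moments(img)
#' @export
hu_moments <- function(img) {
  e <- function(p, q) normalized_moment(img, p, q)
  e20 <- e(2, 0); e02 <- e(0, 2); e11 <- e(1, 1)
  e30 <- e(3, 0); e03 <- e(0, 3); e21 <- e(2, 1); e12 <- e(1, 2)
  h1 <- e20 + e02
  h2 <- (e20 - e02)^2 + 4 * e11^2
  h3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  h4 <- (e30 + e12)^2 + (e21 + e03)^2
  h5 <- (e30 - 3 * e12) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
        (3 * e21 - e03) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  h6 <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
        4 * e11 * (e30 + e12) * (e21 + e03)
  h7 <- (3 * e21 - e03) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
        (e30 - 3 * e12) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  c(h1 = h1, h2 = h2, h3 = h3, h4 = h4, h5 = h5, h6 = h6, h7 = h7)
}
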