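#' Gabor filter parameters
#'
#' A Gabor filter is a complex sinusoid windowed by a Gaussian envelope;
#' the magnitude of its response measures local texture energy at wavelength
#' `lambda` and orientation `theta`.
#'
#' The envelope parameters are rarely reported alongside `(lambda, theta,
#' phi)`; the defaults follow common practice: `gamma = 0.5` (elongated
#' envelope along the stripes) and `sigma = 0.56 * lambda`, the value for
#' which the filter has a spatial-frequency bandwidth of one octave. The
#' kernel is truncated at three standard deviations of the envelope:
#' `halfwidth = ceiling(3 * sigma * max(1, 1/gamma))`.
#'
#' @param lambda wavelength of the sinusoidal component, pixels (> 0).
#' @param theta orientation, radians; 0 gives vertical stripes.
#' @param phi phase offset of the sinusoid, radians.
#' @param sigma Gaussian envelope width, pixels (> 0).
#' @param gamma spatial aspect ratio of the envelope (> 0).
#' @param halfwidth integer kernel half-width; kernel side is
#'   `2 * halfwidth + 1`.
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(lambda, theta = 0, phi = 0,
                         sigma = 0.56 * lambda, gamma = 0.5,
                         halfwidth = NULL) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (is.null(halfwidth))
    halfwidth <- ceiling(3 * sigma * max(1, 1 / gamma))
  halfwidth <- max(1L, as.integer(halfwidth))
  structure(list(lambda = lambda, theta = theta, phi = phi,
                 sigma = sigma, gamma = gamma, halfwidth = halfwidth),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf(
    "Gabor filter: lambda=%.3g px, theta=%.3g rad, phi=%.3g, sigma=%.3g, gamma=%.3g, kernel %dx%d\n",
    x$lambda, x$theta, x$phi, x$sigma, x$gamma,
    2L * x$halfwidth + 1L, 2L * x$halfwidth + 1L))
  invisible(x)
}

#' Complex Gabor kernel
#'
#' Evaluates
#' \deqn{G(x, y) = \exp\!\left(-\frac{x_p^2 + \gamma^2 y_p^2}{2\sigma^2}\right)
#'       \exp\!\left(i\left(\frac{2\pi x_p}{\lambda} + \varphi\right)\right)}
#' with the rotated coordinates \eqn{x_p = x\cos\theta + y\sin\theta} and
#' \eqn{y_p = y\cos\theta - x\sin\theta}, on the integer grid centered at
#' the origin. Rows index `y`, columns index `x`, both running
#' `-halfwidth .. halfwidth`.
#'
#' @param p a [gabor_params()] object.
#' @return complex matrix of side `2 * halfwidth + 1`.
#' @export
gabor_kernel <- function(p) {
  stopifnot(inherits(p, "gabor_params"))
  r <- -p$halfwidth:p$halfwidth
  x <- matrix(r, length(r), length(r), byrow = TRUE)  # columns are x
  y <- matrix(r, length(r), length(r))                # rows are y
  xp <- x * cos(p$theta) + y * sin(p$theta)
  yp <- y * cos(p$theta) - x * sin(p$theta)
  env <- exp(-(xp^2 + p$gamma^2 * yp^2) / (2 * p$sigma^2))
  env * exp(1i * (2 * pi * xp / p$lambda + p$phi))
}

#' Gabor energy response of an image channel
#'
#' Correlates the channel with the real and imaginary parts of the Gabor
#' kernel and fuses the two result matrices into the complex magnitude
#' `sqrt(re^2 + im^2)` (the Gabor energy). Output has the size of the
#' input; borders use replicate padding.
#'
#' @param channel 2-D numeric matrix.
#' @param p a [gabor_params()] object.
#' @param fuse `"magnitude"` (default) or `"sum"` (plain sum of the two
#'   response matrices).
#' @return non-negative (for `"magnitude"`) matrix of the channel's size.
#' @export
gabor_response <- function(channel, p, fuse = c("magnitude", "sum")) {
  if (!is.matrix(channel)) stop("channel must be a 2-D matrix", call. = FALSE)
  fuse <- match.arg(fuse)
  k <- gabor_kernel(p)
  re <- correlate2_fft(channel, Re(k))
  im <- correlate2_fft(channel, Im(k))
  if (fuse == "magnitude") sqrt(re^2 + im^2) else re + im
}

#' 256-bin histogram of a filter response
#'
#' The real-valued response is min-max rescaled to `[0, 255]`, rounded to
#' integers and counted into 256 bins. A constant response (min = max) puts
#' all mass in bin 0. With `normalize = TRUE` counts are divided by the
#' pixel count so histograms from images of different sizes are comparable.
#'
#' @param response 2-D numeric matrix.
#' @param bins number of bins (default 256).
#' @param normalize divide counts by the pixel count (default `FALSE`).
#' @return numeric vector of length `bins`; sums to the pixel count
#'   (raw mode) or 1 (normalized).
#' @export
channel_histogram <- function(response, bins = 256L, normalize = FALSE) {
  if (!is.matrix(response)) stop("response must be a 2-D matrix", call. = FALSE)
  bins <- as.integer(bins)
  v <- as.vector(response)
  rng <- range(v)
  q <- if (rng[2] > rng[1])
    round((v - rng[1]) / (rng[2] - rng[1]) * (bins - 1L))
  else rep(0L, length(v))
  counts <- tabulate(q + 1L, nbins = bins)
  if (normalize) counts / length(v) else as.numeric(counts)
}

#' Default per-channel Gabor parameters
#'
#' One filter per HSI channel: H uses wavelength 13 px at orientation
#' `pi/4`; S wavelength 10 px at `pi/3`; I wavelength 10 px at `pi/12`;
#' all with zero phase. With `lambda_is_reciprocal = TRUE` the wavelength
#' entries are read as spatial frequencies instead (`lambda = 1/value`).
#'
#' @param lambda_is_reciprocal interpret the wavelength column as `1/lambda`.
#' @return named list of three [gabor_params()] objects (`h`, `s`, `i`).
#' @export
default_gabor_bank <- function(lambda_is_reciprocal = FALSE) {
  lam <- c(h = 13, s = 10, i = 10)
  if (lambda_is_reciprocal) lam <- 1 / lam
  list(h = gabor_params(lam[["h"]], pi / 4, 0),
       s = gabor_params(lam[["s"]], pi / 3, 0),
       i = gabor_params(lam[["i"]], pi / 12, 0))
}

#' 768-dimensional Gabor texture feature
#'
#' Filters each HSI channel with its own Gabor filter and concatenates the
#' three 256-bin response histograms: H-channel bins 1-256, S-channel bins
#' 257-512, I-channel bins 513-768. The hue channel is rescaled from
#' `[0, 2*pi)` to `[0, 255]` before filtering so all three channels share
#' the same dynamic range.
#'
#' @param hsi list with matrices `h`, `s`, `i` as returned by
#'   [rgb_to_hsi()].
#' @param bank named list of three [gabor_params()] (`h`, `s`, `i`);
#'   default [default_gabor_bank()].
#' @param normalize normalize each histogram block to sum 1 (default
#'   `FALSE`, raw counts).
#' @param fuse response fusion mode, see [gabor_response()].
#' @return named numeric vector of length 768 (`f1` .. `f768`).
#' @export
gabor_features <- function(hsi, bank = default_gabor_bank(),
                           normalize = FALSE, fuse = "magnitude") {
  stopifnot(is.list(hsi), all(c("h", "s", "i") %in% names(hsi)))
  chans <- list(h = hsi$h * 255 / (2 * pi), s = hsi$s * 255, i = hsi$i)
  out <- unlist(lapply(c("h", "s", "i"), function(ch) {
    resp <- gabor_response(chans[[ch]], bank[[ch]], fuse = fuse)
    channel_histogram(resp, 256L, normalize = normalize)
  }))
  names(out) <- paste0("f", seq_len(768L))
  out
}
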