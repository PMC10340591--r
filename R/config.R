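#' Pipeline configuration
#'
#' Collects every tunable knob of the feature pipeline in one list.
#'
#' @param grayscale_coeffs RGB-to-gray weights; default BT.601
#'   `(0.299, 0.587, 0.114)`.
#' @param crop_gap maximum gap between nonzero edge coordinates treated as
#'   one object (pixels, default 10).
#' @param morph_radius disk radius for the morphological mask cleanup
#'   (pixels, default 3).
#' @param sobel_on run Sobel on the binarized mask (`"mask"`, default) or
#'   on the grayscale image (`"gray"`).
#' @param gabor_bank per-channel Gabor filters, see [default_gabor_bank()].
#' @param gabor_normalize normalize each 256-bin histogram block to sum 1
#'   so crops of different sizes are comparable (default `TRUE` for the
#'   end-to-end pipeline).
#' @param gabor_fuse fusion of real/imaginary responses, `"magnitude"` or
#'   `"sum"`.
#' @param preprocess run the cropping/background stage inside
#'   [extract_features()] (default `TRUE`; set `FALSE` for images already
#'   preprocessed).
#' @return a named list of class `berry_config`.
#' @export
berry_config <- function(grayscale_coeffs = c(0.299, 0.587, 0.114),
                         crop_gap = 10L,
                         morph_radius = 3L,
                         sobel_on = c("mask", "gray"),
                         gabor_bank = default_gabor_bank(),
                         gabor_normalize = TRUE,
                         gabor_fuse = "magnitude",
                         preprocess = TRUE) {
  structure(list(grayscale_coeffs = grayscale_coeffs,
                 crop_gap = crop_gap,
                 morph_radius = morph_radius,
                 sobel_on = match.arg(sobel_on),
                 gabor_bank = gabor_bank,
                 gabor_normalize = gabor_normalize,
                 gabor_fuse = gabor_fuse,
                 preprocess = preprocess),
            class = "berry_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [berry_config()]; the Gabor bank
#' is given as `gabor: {h: {lambda, theta, phi}, s: ..., i: ...}` with
#' optional `sigma` and `gamma` per channel and a top-level
#' `lambda_is_reciprocal` flag.
#'
#' @param path YAML file path.
#' @return a `berry_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- berry_config()
  for (key in intersect(names(y), c("grayscale_coeffs", "crop_gap",
                                    "morph_radius", "sobel_on",
                                    "gabor_normalize", "gabor_fuse",
                                    "preprocess")))
    cfg[[key]] <- y[[key]]
  if (!is.null(y$gabor)) {
    recip <- isTRUE(y$lambda_is_reciprocal)
    cfg$gabor_bank <- lapply(y$gabor[c("h", "s", "i")], function(g) {
      lam <- if (recip) 1 / g$lambda else g$lambda
      do.call(gabor_params, c(list(lambda = lam),
                              g[intersect(names(g),
                                          c("theta", "phi", "sigma", "gamma"))]))
    })
  }
  cfg
}
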