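#' Convert an RGB image to grayscale
#'
#' Weighted channel sum `c_R*R + c_G*G + c_B*B`. The default coefficients are
#' the ITU-R BT.601 luma weights (0.299, 0.587, 0.114). A variant triple with
#' 0.578 for green is in circulation in parts of the fruit-imaging
#' literature; pass it via `coeffs` for bit-faithful replication of results
#' computed with it.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param coeffs length-3 non-negative weights for R, G, B.
#' @return `H x W` grayscale matrix.
#' @examples
#' img <- array(128, dim = c(16, 16, 3))
#' range(to_grayscale(img))
#' @export
to_grayscale <- function(img, coeffs = c(0.299, 0.587, 0.114)) {
  assert_rgb(img)
  stopifnot(length(coeffs) == 3L, all(coeffs >= 0))
  coeffs[1] * img[, , 1] + coeffs[2] * img[, , 2] + coeffs[3] * img[, , 3]
}

#' Otsu threshold of a grayscale image
#'
#' Selects the gray level `k*` maximizing the between-class variance
#' \deqn{\sigma_B^2(k) = P_1(m_1 - m_G)^2 + P_2(m_2 - m_G)^2
#'                     = P_1 P_2 (m_1 - m_2)^2,}
#' equivalently the separability ratio \eqn{\eta(k) = \sigma_B^2(k) /
#' \sigma_G^2}. Pixels are quantized to `levels` integer bins by rounding
#' before the histogram is formed. Ties in the argmax are broken toward the
#' smallest `k`.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @param levels number of gray levels (default 256).
#' @return list with `k` (threshold gray level, class 1 is `<= k`) and
#'   `eta` (maximal separability ratio, in `[0, 1]`).
#' @examples
#' img <- matrix(c(rep(0, 128), rep(255, 128)), 16, 16)
#' otsu_threshold(img)   # eta = 1: perfectly separable
#' @export
otsu_threshold <- function(img, levels = 256L) {
  assert_gray(img)
  L <- as.integer(levels)
  stopifnot(L >= 2L)
  g <- round(as.vector(img) * (L - 1L) / 255)
  g[g < 0] <- 0; g[g > L - 1L] <- L - 1L
  counts <- tabulate(g + 1L, nbins = L)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L)
    stop("no threshold exists: image is constant after quantization",
         call. = FALSE)
  i <- 0:(L - 1L)
  P1 <- cumsum(p)                 # P1(k), k = 0 .. L-1
  mu <- cumsum(i * p)             # cumulative first moment
  mG <- mu[L]
  sigmaG2 <- sum((i - mG)^2 * p)
  # sigma_B^2(k) = (mG*P1 - mu)^2 / (P1*(1-P1)); defined only for 0 < P1 < 1
  denom <- P1 * (1 - P1)
  sigmaB2 <- ifelse(denom > 0, (mG * P1 - mu)^2 / denom, 0)
  kstar <- which.max(sigmaB2) - 1L        # smallest k on ties
  eta <- sigmaB2[kstar + 1L] / sigmaG2
  kgray <- kstar * 255 / (L - 1L)         # back to the [0,255] scale
  list(k = kgray, eta = eta, sigma_b2 = sigmaB2, sigma_g2 = sigmaG2)
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels strictly greater than `k` become 1, the rest 0. With the Otsu
#' threshold this puts the bright (background) class at 1 for a light
#' background scene.
#'
#' @param img grayscale matrix.
#' @param k threshold gray level.
#' @return `H x W` matrix of 0/1.
#' @export
binarize <- function(img, k) {
  assert_gray(img)
  stopifnot(k >= 0, k <= 255)
  (img > k) + 0
}

# 3x3 Sobel kernels: gx responds to horizontal gradients (vertical edges)
sobel_gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
sobel_gy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)

#' Sobel edge magnitude
#'
#' Correlates the image with the horizontal and vertical 3x3 Sobel kernels
#' and returns the gradient magnitude `sqrt(Gx^2 + Gy^2)`. Borders use
#' replicate padding so the output has the size of the input and edge
#' coordinates stay aligned with the source raster.
#'
#' @param img 2-D matrix (binary mask or grayscale).
#' @return non-negative `H x W` edge-magnitude matrix.
#' @export
sobel_edges <- function(img) {
  if (!is.matrix(img)) stop("img must be a 2-D matrix", call. = FALSE)
  gx <- correlate2_shift(img, sobel_gx)
  gy <- correlate2_shift(img, sobel_gy)
  sqrt(gx^2 + gy^2)
}

# largest run of coordinates in which consecutive members are <= gap apart;
# ties broken toward the earliest run
largest_run <- function(coords, gap) {
  breaks <- which(diff(coords) > gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(coords))
  best <- which.max(ends - starts)
  c(coords[starts[best]], coords[ends[best]])
}

#' Bounding box of the main edge region
#'
#' Finds the nonzero rows and columns of an edge image and returns the
#' bounding box of the largest coherent run in each direction: consecutive
#' nonzero coordinates more than `gap_thresh` apart are treated as separate
#' runs, and isolated runs away from the largest one are discarded as noise.
#'
#' @param edges non-negative edge-magnitude matrix.
#' @param gap_thresh maximum gap (pixels) between nonzero coordinates within
#'   one run (default 10).
#' @param tol values `<= tol` count as zero.
#' @return list with `xmin`, `xmax` (columns), `ymin`, `ymax` (rows),
#'   1-based inclusive.
#' @export
crop_bounds <- function(edges, gap_thresh = 10L, tol = 1e-9) {
  if (!is.matrix(edges)) stop("edges must be a 2-D matrix", call. = FALSE)
  nz <- edges > tol
  cols <- which(colSums(nz) > 0)
  rows <- which(rowSums(nz) > 0)
  if (length(cols) == 0L) stop("no object found", call. = FALSE)
  xr <- largest_run(cols, gap_thresh)
  yr <- largest_run(rows, gap_thresh)
  list(xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2])
}

#' Crop an image to a bounding box
#'
#' @param img matrix or `H x W x C` array.
#' @param box list with `xmin`, `xmax` (columns), `ymin`, `ymax` (rows).
#' @return the cropped image.
#' @export
crop_image <- function(img, box) {
  if (is.matrix(img)) img[box$ymin:box$ymax, box$xmin:box$xmax, drop = FALSE]
  else img[box$ymin:box$ymax, box$xmin:box$xmax, , drop = FALSE]
}

#' Clean a foreground mask and black out the background
#'
#' The mask is morphologically closed then opened with a disk structuring
#' element (removing pinholes and salt noise up to the disk radius), and
#' every image pixel where the cleaned mask is 0 is set to black (0,0,0).
#' Fruit pixels are untouched.
#'
#' @param img `H x W x 3` RGB array.
#' @param mask `H x W` 0/1 foreground mask (1 = fruit).
#' @param radius disk radius of the structuring element, pixels (default 3).
#' @return list with `img` (background-unified RGB array) and `mask` (the
#'   cleaned 0/1 mask).
#' @export
unify_background <- function(img, mask, radius = 3L) {
  assert_rgb(img)
  if (!is.matrix(mask) || !all(dim(mask) == dim(img)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be 0/1", call. = FALSE)
  if (radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- t(mask)  # EBImage stores x (columns) first
    m <- EBImage::opening(EBImage::closing(m, kern), kern)
    mask <- t(as.matrix(m))
  }
  out <- img * as.vector(mask)  # recycles across the 3 channels
  list(img = out, mask = mask)
}

#' Preprocess a raw fruit photograph
#'
#' Full preprocessing chain for a single bright-background fruit image:
#' grayscale conversion, Otsu thresholding, binarization, Sobel edge
#' detection, noise-robust bounding-box cropping, and morphological
#' background unification. The result is a tight crop of the fruit on an
#' exactly black background.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param cfg configuration list, see [berry_config()]. Relevant keys:
#'   `grayscale_coeffs`, `crop_gap`, `morph_radius`, `sobel_on` ("mask" to
#'   run Sobel on the binarized image, "gray" on the grayscale).
#' @return list with `img` (cropped, background-unified RGB array), `mask`
#'   (cleaned 0/1 foreground mask of the crop), `box` (crop bounding box),
#'   `otsu_k` (threshold), `otsu_eta` (separability ratio).
#' @examples
#' syn <- generate_image(class_recipe("demo"), seed = 1)
#' pp <- preprocess_image(syn$img)
#' dim(pp$img); pp$box
#' @export
preprocess_image <- function(img, cfg = berry_config()) {
  assert_rgb(img)
  gray <- to_grayscale(img, cfg$grayscale_coeffs)
  ot <- tryCatch(otsu_threshold(gray),
                 error = function(e) stop("no object found", call. = FALSE))
  bw <- binarize(gray, ot$k)       # 1 = the brighter of the two classes
  # the background is whichever class dominates the image border (bright
  # for a raw photograph, black for an already-preprocessed crop)
  nr <- nrow(bw); nc <- ncol(bw)
  border <- c(bw[1, ], bw[nr, ], bw[, 1], bw[, nc])
  fgraw <- if (mean(border) >= 0.5) 1 - bw else bw
  src <- if (identical(cfg$sobel_on, "gray")) gray else bw
  edges <- sobel_edges(src)
  # a fruit cropped tight to the frame has its contour cut open by the
  # frame; foreground pixels on the border complete the contour so the
  # gap rule does not split the object
  cut <- matrix(0, nr, nc)
  cut[c(1L, nr), ] <- fgraw[c(1L, nr), ]
  cut[, c(1L, nc)] <- fgraw[, c(1L, nc)]
  edges <- pmax(edges, 4 * cut)
  box <- crop_bounds(edges, cfg$crop_gap)
  cropped <- crop_image(img, box)
  fg <- crop_image(fgraw, box)     # fruit mask inside the crop
  uni <- unify_background(cropped, fg, cfg$morph_radius)
  list(img = uni$img, mask = uni$mask, box = box,
       otsu_k = ot$k, otsu_eta = ot$eta)
}
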