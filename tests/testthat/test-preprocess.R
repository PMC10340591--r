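test_that("grayscale conversion is the stated channel combination", {
  img <- pixel_image(c(0, 0, 0))
  expect_equal(to_grayscale(img, c(0.299, 0.578, 0.114))[1, 1], 0)

  img <- pixel_image(c(255, 255, 255))
  # the legacy 0.578 triple sums to 0.991, so white maps to 252.705
  expect_equal(to_grayscale(img, c(0.299, 0.578, 0.114))[1, 1], 252.705)
  # the BT.601 default keeps white at 255
  expect_equal(to_grayscale(img)[1, 1], 255)

  img <- pixel_image(c(100, 50, 200))
  expect_equal(to_grayscale(img)[1, 1],
               0.299 * 100 + 0.587 * 50 + 0.114 * 200)
  expect_equal(to_grayscale(img)[1, 1], 82.05)

  expect_error(to_grayscale(matrix(0, 16, 16)), "H x W x 3")
})

test_that("Otsu threshold maximizes between-class separability", {
  img <- matrix(c(rep(0, 128), rep(255, 128)), 16, 16)
  ot <- otsu_threshold(img)
  expect_equal(ot$eta, 1)  # perfectly separable bimodal image

  img <- matrix(c(10, 10, 10, 200), 2, 2)
  img <- img[rep(1:2, 8), rep(1:2, 8)]  # tile up to >= 16x16
  ot <- otsu_threshold(img)
  expect_gte(ot$k, 10)
  expect_lt(ot$k, 200)

  expect_error(otsu_threshold(matrix(7, 16, 16)), "no threshold")
})

test_that("Otsu agrees with an exhaustive brute-force scan", {
  set.seed(101)
  for (rep in 1:50) {
    img <- matrix(sample(0:255, 24 * 24, replace = TRUE,
                         prob = runif(256)^2), 24, 24)
    ot <- otsu_threshold(img)
    bf <- brute_otsu(img)
    expect_equal(ot$k, bf$k)
    expect_equal(ot$eta, bf$eta, tolerance = 1e-10)
  }
})

test_that("binarization uses the strict-greater convention", {
  expect_equal(binarize(matrix(0, 16, 16), 0), matrix(0, 16, 16))
  img <- matrix(rep(c(0, 128, 255), length.out = 18), 18, 18)
  expect_equal(sort(unique(as.vector(binarize(img, 128)))), c(0, 1))
  expect_equal(binarize(img, 128)[1:3, 1], c(0, 0, 1))
})

test_that("Otsu binarization recovers a synthetic blob's area", {
  g <- generate_image(class_recipe("blob", noise_sd = 2,
                                   ridge_contrast = 0.3), seed = 5)
  gray <- to_grayscale(g$img)
  ot <- otsu_threshold(gray)
  fg <- 1 - binarize(gray, ot$k)   # fruit is the dark class
  expect_equal(sum(fg), sum(g$mask), tolerance = 0.02)
})

test_that("Sobel magnitude behaves like a gradient operator", {
  expect_equal(sobel_edges(matrix(5, 10, 10)), matrix(0, 10, 10))

  # vertical step 0|1: |Gx| on the two columns adjacent to the step is the
  # kernel column sum 1+2+1 = 4
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  e <- sobel_edges(step)
  expect_equal(max(e), 4)
  expect_true(all(e[, c(4, 5)] == 4))
  expect_true(all(e[, c(1:2, 7:8)] == 0))

  # adding a constant leaves the magnitude unchanged
  set.seed(1)
  m <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(sobel_edges(m), sobel_edges(m + 17))

  # responses confined to within 1 pixel of a square's boundary
  sq <- matrix(0, 20, 20); sq[8:13, 6:15] <- 1
  e <- sobel_edges(sq)
  interior <- e[10:11, 8:13]
  expect_true(all(interior == 0))
  expect_true(all(e[1:5, ] == 0))
})

test_that("Sobel matches the brute-force correlation oracle", {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)
  set.seed(2)
  for (rep in 1:5) {
    m <- matrix(sample(0:1, 12 * 15, replace = TRUE), 12, 15)
    expect_equal(sobel_edges(m),
                 sqrt(brute_correlate(m, gx)^2 + brute_correlate(m, gy)^2))
  }
})

test_that("crop bounds keep the main run and reject distant noise", {
  mk <- function(cols) {
    e <- matrix(0, 30, 60); e[15, cols] <- 1; e
  }
  b <- crop_bounds(mk(5:20))
  expect_equal(c(b$xmin, b$xmax), c(5, 20))

  b <- crop_bounds(mk(c(5:20, 45)))         # gap 25 > 10: noise
  expect_equal(c(b$xmin, b$xmax), c(5, 20))

  b <- crop_bounds(mk(c(5:20, 25:30)))      # gap 5 <= 10: merged
  expect_equal(c(b$xmin, b$xmax), c(5, 30))

  expect_error(crop_bounds(matrix(0, 10, 10)), "no object")
})

test_that("crop bounds contain the main run and cropping is idempotent", {
  set.seed(3)
  for (rep in 1:10) {
    # closed rectangular contour (every bbox row/column touched), plus an
    # isolated noise pixel well beyond the gap threshold
    e <- matrix(0, 40, 40)
    r0 <- sample(14:20, 1); c0 <- sample(14:20, 1)
    r1 <- r0 + 12; c1 <- c0 + 9
    e[r0:r1, c(c0, c1)] <- 1
    e[c(r0, r1), c0:c1] <- 1
    e[1, 1] <- 1
    b <- crop_bounds(e)
    expect_equal(c(b$ymin, b$ymax, b$xmin, b$xmax), c(r0, r1, c0, c1))
    cropped <- crop_image(e, b)
    b2 <- crop_bounds(cropped)
    expect_equal(dim(crop_image(cropped, b2)), dim(cropped))
  }
})

test_that("background unification blackens exactly the cleaned mask", {
  img <- pixel_image(c(120, 80, 60), side = 20)
  ones <- matrix(1, 20, 20)
  expect_equal(unify_background(img, ones, radius = 2)$img, img)
  zero <- matrix(0, 20, 20)
  expect_equal(unify_background(img, zero, radius = 2)$img,
               array(0, dim = c(20, 20, 3)))
  expect_error(unify_background(img, matrix(1, 5, 5), 2), "dimensions")

  # salt noise in the background and pinholes in the blob, radius 2
  mask <- matrix(0, 20, 20); mask[5:16, 6:15] <- 1
  mask[10, 10] <- 0          # pinhole
  mask[2, 18] <- 1           # salt
  res <- unify_background(img, mask, radius = 2)
  expect_equal(res$mask[2, 18], 0)   # salt removed by opening
  expect_equal(res$mask[10, 10], 1)  # pinhole closed
  # nonblack pixel count equals cleaned mask area in every channel
  expect_equal(sum(rowSums(res$img, dims = 2) > 0), sum(res$mask))
  expect_true(all(res$img[res$mask == 0] == 0))
})

test_that("morphological cleanup matches a brute-force closing/opening", {
  se <- EBImage::makeBrush(5, "disc")
  set.seed(4)
  mask <- matrix(0, 20, 20); mask[6:15, 5:16] <- 1
  mask[sample(400, 6)] <- 1  # sprinkle noise
  img <- pixel_image(c(200, 100, 50), side = 20)
  res <- unify_background(img, mask, radius = 2)
  ref <- brute_erode(brute_dilate(mask, se), se)   # closing
  ref <- brute_dilate(brute_erode(ref, se), se)    # then opening
  expect_equal(res$mask, ref)
})

test_that("full preprocessing recovers the generated blob", {
  g <- generate_image(class_recipe("clean", noise_sd = 0,
                                   ridge_contrast = 0), seed = 9)
  pp <- preprocess_image(g$img)
  expect_lte(abs(pp$box$xmin - g$bbox$xmin), 2)
  expect_lte(abs(pp$box$xmax - g$bbox$xmax), 2)
  expect_lte(abs(pp$box$ymin - g$bbox$ymin), 2)
  expect_lte(abs(pp$box$ymax - g$bbox$ymax), 2)
  # background is exactly black
  expect_true(all(pp$img[pp$mask == 0] == 0))

  # a second pass over the already-cropped black-background image keeps
  # essentially the whole area
  pp2 <- preprocess_image(pp$img)
  a1 <- prod(dim(pp$img)[1:2]); a2 <- prod(dim(pp2$img)[1:2])
  expect_gte(a2 / a1, 0.95)

  expect_error(preprocess_image(array(255, dim = c(32, 32, 3))),
               "no object found")
})
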