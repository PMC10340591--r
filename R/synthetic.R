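#' Recipe for one synthetic fruit class
#'
#' Describes the ellipse geometry, ridge texture and color of a synthetic
#' fruit class. Rendered fruits are elliptical blobs on a near-white
#' background whose surface brightness is modulated by a single-orientation
#' sinusoidal ridge field — the simplest texture a single Gabor filter per
#' channel can provably discriminate.
#'
#' @param name class label.
#' @param axis_ratio major/minor axis ratio of the ellipse (>= 1).
#' @param mean_diameter geometric-mean diameter of the ellipse, pixels
#'   (>= 32).
#' @param ridge_wavelength wavelength of the ridge pattern, pixels (>= 2).
#' @param ridge_orientation orientation of the ridges, radians.
#' @param ridge_contrast modulation depth of the ridges, in `[0, 1]`.
#' @param base_color RGB triple of the fruit surface in `[0, 255]`.
#' @param noise_sd per-pixel Gaussian noise standard deviation (gray
#'   levels).
#' @return object of class `class_recipe`.
#' @export
class_recipe <- function(name,
                         axis_ratio = 1.4,
                         mean_diameter = 96,
                         ridge_wavelength = 10,
                         ridge_orientation = pi / 4,
                         ridge_contrast = 0.4,
                         base_color = c(190, 70, 60),
                         noise_sd = 3) {
  stopifnot(mean_diameter >= 32, ridge_wavelength >= 2,
            ridge_contrast >= 0, ridge_contrast <= 1,
            axis_ratio >= 1, length(base_color) == 3L)
  structure(list(name = name, axis_ratio = axis_ratio,
                 mean_diameter = mean_diameter,
                 ridge_wavelength = ridge_wavelength,
                 ridge_orientation = ridge_orientation,
                 ridge_contrast = ridge_contrast,
                 base_color = base_color, noise_sd = noise_sd),
            class = "class_recipe")
}

#' Default four-class recipe set
#'
#' Emulates a 4-origin single-fruit study: two "rugged" classes with short
#' ridge wavelength (8 px) and strong contrast, and two "delicate" classes
#' with long wavelength (20 px) and weak contrast, each pair separated by
#' aspect ratio, size and a slight color shift.
#'
#' @return named list of four [class_recipe()] objects (`GS`, `NM`, `NX`,
#'   `QH`).
#' @export
default_recipes <- function() {
  list(
    GS = class_recipe("GS", axis_ratio = 1.25, mean_diameter = 84,
                      ridge_wavelength = 20, ridge_orientation = pi / 4,
                      ridge_contrast = 0.25,
                      base_color = c(195, 75, 60), noise_sd = 3),
    NM = class_recipe("NM", axis_ratio = 1.2, mean_diameter = 96,
                      ridge_wavelength = 8, ridge_orientation = pi / 4,
                      ridge_contrast = 0.6,
                      base_color = c(170, 55, 50), noise_sd = 3),
    NX = class_recipe("NX", axis_ratio = 1.7, mean_diameter = 88,
                      ridge_wavelength = 20, ridge_orientation = pi / 3,
                      ridge_contrast = 0.2,
                      base_color = c(205, 90, 70), noise_sd = 3),
    QH = class_recipe("QH", axis_ratio = 1.5, mean_diameter = 104,
                      ridge_wavelength = 8, ridge_orientation = pi / 3,
                      ridge_contrast = 0.45,
                      base_color = c(150, 60, 55), noise_sd = 3)
  )
}

#' Render one synthetic fruit image
#'
#' Draws a single ellipse with a sinusoidal ridge texture on a near-white
#' (245-255) background, with seeded position jitter, in-plane rotation
#' jitter and Gaussian pixel noise. Ground truth (exact foreground mask and
#' bounding box) is returned for preprocessing tests.
#'
#' @param recipe a [class_recipe()].
#' @param seed integer seed; the same seed reproduces the image exactly.
#' @param canvas `(H, W)` canvas size in pixels.
#' @return list with `img` (`H x W x 3` RGB array), `mask` (ground-truth
#'   0/1 foreground), `bbox` (list `xmin/xmax/ymin/ymax`, 1-based columns/
#'   rows).
#' @export
generate_image <- function(recipe, seed = 1L, canvas = c(160L, 160L)) {
  stopifnot(inherits(recipe, "class_recipe"))
  H <- canvas[1]; W <- canvas[2]
  a <- recipe$mean_diameter * sqrt(recipe$axis_ratio) / 2   # semi-major
  b <- recipe$mean_diameter / sqrt(recipe$axis_ratio) / 2   # semi-minor
  if (2 * a + 16 > min(H, W))
    stop("blob does not fit the canvas with margin", call. = FALSE)
  set.seed(as.integer(seed))
  jmax <- max(0, (min(H, W) - 2 * a - 16) / 2)
  cy <- H / 2 + runif(1, -1, 1) * min(6, jmax)
  cx <- W / 2 + runif(1, -1, 1) * min(6, jmax)
  rot <- runif(1, -0.3, 0.3)                 # ellipse orientation jitter
  ridge_th <- recipe$ridge_orientation + runif(1, -0.05, 0.05)

  y <- matrix(seq_len(H), H, W) - cy         # rows
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- x * cos(rot) + y * sin(rot)
  v <- -x * sin(rot) + y * cos(rot)
  inside <- (u / a)^2 + (v / b)^2 <= 1

  phase0 <- runif(1, 0, 2 * pi)
  ridge <- sin(2 * pi * (x * cos(ridge_th) + y * sin(ridge_th)) /
               recipe$ridge_wavelength + phase0)
  shade <- 1 - recipe$ridge_contrast * 0.5 * (1 + ridge)  # in [1-c, 1]
  # mild limb darkening so the blob is not flat even at zero contrast noise
  limb <- 1 - 0.15 * ((u / a)^2 + (v / b)^2)

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    bg <- matrix(runif(H * W, 245, 255), H, W)
    fg <- recipe$base_color[ch] * shade * limb
    plane <- ifelse(inside, fg, bg)
    if (recipe$noise_sd > 0)
      plane <- plane + matrix(rnorm(H * W, 0, recipe$noise_sd), H, W)
    img[, , ch] <- pmin(255, pmax(0, plane))
  }
  rows <- which(rowSums(inside) > 0)
  cols <- which(colSums(inside) > 0)
  list(img = img, mask = inside + 0,
       bbox = list(xmin = min(cols), xmax = max(cols),
                   ymin = min(rows), ymax = max(rows)))
}

#' Generate a labeled synthetic dataset
#'
#' Renders `per_class` images for each recipe and returns them with a
#' manifest. With `dir` set, images are written as PNGs plus a
#' `manifest.csv` (and the recipes as `recipes.yaml`), mirroring an on-disk
#' image collection; otherwise images stay in memory.
#'
#' @param recipes named list of [class_recipe()] objects.
#' @param per_class images per class (default 90).
#' @param seed master seed; image `k` of class `j` uses a seed derived
#'   deterministically from it.
#' @param canvas canvas size passed to [generate_image()].
#' @param dir optional output directory for PNGs + manifest.
#' @return list with `images` (list of RGB arrays; `NULL` entries when
#'   written to disk), `manifest` (data.frame: id, label, seed, bbox
#'   columns, mask_area, path).
#' @export
generate_dataset <- function(recipes = default_recipes(), per_class = 90L,
                             seed = 1L, canvas = c(160L, 160L), dir = NULL) {
  stopifnot(length(recipes) >= 2L, !anyDuplicated(names(recipes)))
  rows <- list(); imgs <- list()
  n <- 0L
  for (j in seq_along(recipes)) {
    rec <- recipes[[j]]
    for (k in seq_len(per_class)) {
      n <- n + 1L
      sseed <- (as.integer(seed) * 7919L + j * 1009L + k) %% .Machine$integer.max
      g <- generate_image(rec, seed = sseed, canvas = canvas)
      id <- sprintf("%s_%03d", names(recipes)[j], k)
      path <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        path <- file.path(dir, paste0(id, ".png"))
        write_rgb(g$img, path)
        imgs[[n]] <- NA  # on disk
      } else imgs[[n]] <- g$img
      rows[[n]] <- data.frame(
        id = id, label = names(recipes)[j], seed = sseed,
        xmin = g$bbox$xmin, xmax = g$bbox$xmax,
        ymin = g$bbox$ymin, ymax = g$bbox$ymax,
        mask_area = sum(g$mask), path = path,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(lapply(recipes, unclass), file.path(dir, "recipes.yaml"))
    imgs <- NULL
  }
  list(images = imgs, manifest = manifest)
}
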