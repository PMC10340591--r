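Package: berryprint
Title: Geographic-Origin Identification of Single-Fruit Images from
    Color, Texture and Shape Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for identifying the geographic origin of single-fruit
    photographs (developed for dried wolfberry, Lycium barbarum). Raw images
    on a light background are cropped via Otsu thresholding and Sobel edge
    detection and set on a uniform black background; the crop is transformed
    to the HSI color space; one Gabor filter per channel yields a 768-bin
    texture histogram; seven Hu invariant moments add shape information; and
    a random forest is trained and evaluated under a repeated stratified
    train/test split protocol with per-sample misclassification analysis.
    A seeded synthetic-fruit generator provides labeled fixture datasets
    with class-specific ridge texture and ellipse shape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
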