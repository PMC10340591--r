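---
title: "How berryprint identifies fruit origin from single-fruit images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How berryprint identifies fruit origin from single-fruit images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryprint)
```

## The problem

The geographic origin of a medicinal fruit such as dried wolfberry
(*Lycium barbarum*) matters for its composition and market value, yet
origins are traditionally judged by eye. Fruits from different growing
regions differ subtly in surface texture (ruggedness and ridge scale),
shape (elongation, size) and color. berryprint turns a photograph of a
single fruit on a light background into a 775-dimensional descriptor of
those properties and classifies it with a random forest.

## The pipeline

**1. Preprocessing.** The photograph is converted to grayscale
(`to_grayscale()`, BT.601 weights 0.299/0.587/0.114 by default), an Otsu
threshold is chosen by maximizing the between-class variance
$\sigma_B^2(k) = P_1(m_1-m_G)^2 + P_2(m_2-m_G)^2$ relative to the global
variance, and the image is binarized with the strict-greater convention
(pixel $> k^\ast \rightarrow 1$). Sobel kernels extract the fruit contour
from the binary mask; the crop box is the bounding box of the largest run
of nonzero edge rows/columns in which consecutive coordinates are at most
`crop_gap = 10` px apart — isolated specks farther away are discarded as
noise. Finally the foreground mask is morphologically closed then opened
with a disk (radius 3 px at fixture scale) and everything outside it is
set to exact black, so the background contributes a single constant value
downstream.

Two robustness refinements are part of the design. The foreground class is
taken to be whichever binary class does *not* dominate the image border,
so the chain also behaves sensibly on images whose background is already
black. And where the foreground touches the frame, its border pixels are
added to the edge map: a contour cut open by the frame would otherwise
split into two coordinate runs and trip the gap rule.

**2. HSI transform.** `rgb_to_hsi()` maps each pixel to hue (an angle),
saturation ($1 - 3\min(R,G,B)/(R+G+B)$) and intensity (the exact channel
mean). Working in HSI decouples chromatic identity from brightness and so
damps illumination differences between shots. Degenerate pixels get fixed
fallbacks (black $\mapsto (0,0,0)$; gray hue $\mapsto 0$), never NaN,
because the preprocessed background is exactly black.

**3. Texture: one Gabor filter per channel.** Each HSI channel is
correlated with the real and imaginary parts of a single complex Gabor
kernel and the two responses are fused into the energy
$\sqrt{\mathrm{re}^2+\mathrm{im}^2}$. The per-channel defaults are
$\lambda = 13$ px at $\theta=\pi/4$ for H, $10$ px at $\pi/3$ for S and
$10$ px at $\pi/12$ for I, phase 0. The envelope parameters are rarely
reported with such settings, so the package fixes them by convention:
$\gamma = 0.5$ and $\sigma = 0.56\lambda$ (a one-octave frequency
bandwidth), kernel truncated at $3\sigma$. Hue is rescaled from
$[0,2\pi)$ to $[0,255]$ before filtering so the three channels share one
dynamic range. Each response is min–max rescaled to $[0,255]$, rounded,
and counted into 256 bins; the three histograms concatenate to the
768-dimensional texture feature. Raw counts are the low-level default;
the pipeline-level configuration (`berry_config()`) normalizes each block
to sum 1, because crops of different fruits have different pixel counts
and unnormalized histograms would mostly encode crop area.

**4. Shape: Hu invariant moments.** The grayscale of the preprocessed
crop is reduced to the seven Hu invariants of its normalized central
moments ($e_{pq} = \mu_{pq}/\mu_{00}^{(p+q+2)/2}$). These are invariant
to translation, rotation and scale; the seventh flips sign under
mirroring. Values are used raw — no log compression — since they feed a
tree ensemble, which is monotone-transform-insensitive.

**5. Classification and evaluation.** Features fuse texture-first into a
775-vector. A random forest (`randomForest`, the classification variant;
`nTree = 2000`, `mtry = 50` by default) is trained on a stratified 8:2
split and the whole split–train–test cycle is repeated with fresh seeds
(`repeated_eval()`), yielding the mean accuracy, a pooled
predicted-by-actual confusion matrix and per-sample error rates (how
often each sample was drawn into a test set vs. misclassified) — the
basis for flagging chronically confusable samples.
`hyperparameter_grid()` and `proportion_sweep()` reproduce the
hyperparameter table and the training-fraction robustness curve.
Stratification is per class; trees are scale-invariant so no feature
scaling is applied. Seeding is explicit everywhere: split seed = master
seed + repeat index, forest seeded independently, so a report is
bit-reproducible from its master seed.

## The synthetic study set

The generator (`generate_image()`, `generate_dataset()`) emulates a
four-origin, 90-images-per-origin study: one ellipse per image on a
near-white (245–255) noisy background, its surface modulated by a
single-orientation sinusoidal ridge field plus Gaussian pixel noise, with
seeded position and rotation jitter. The default recipes encode the
field-observed contrast between origins — two "rugged" classes (ridge
wavelength 8 px, high contrast) and two "delicate" ones (20 px, low
contrast) — further separated by aspect ratio, mean diameter and slight
color shifts. A sinusoidal ridge field is deliberately the *simplest*
texture a single Gabor filter per channel can discriminate: the fixtures
test feature sensitivity, not photorealism. Canvas size defaults to
160×160 px with fruit diameters of 84–104 px, a scale at which the full
4×90 set featurizes in about a minute.

What passing tests on these fixtures do **not** show: robustness to
shadows, specular highlights, multi-fruit scenes, camera optics, or
natural texture variation. Real wolfberry images also come as two views
per berry; the synthetic set has one view per fruit and splits are
per-image, so grouped-view leakage control is out of scope here.

## Numerical and protocol choices

- Otsu ties are broken toward the smallest threshold; a constant image
  has no threshold and raises an error.
- Sobel uses exact shift-and-add correlation with replicate padding
  (constant images give identically zero gradients); the large Gabor
  kernels use FFT correlation, verified against a spatial brute-force
  oracle in the tests.
- A constant filter response maps to histogram bin 0.
- Grid ties are broken toward the smaller `n_trees`, then smaller `mtry`.
- Crop coordinates are 1-based inclusive, the native R matrix convention.
- The degenerate-control protocol (four classes rendered from one
  identical recipe) should sit at chance, ~25% for four classes; it
  guards against label leakage through seeds or identifiers.

Problem sizes used by the repeated protocols in the shipped tests and in
`scripts/acceptance.R` — 20–30 repeats for the main 8:2 evaluation, 2–3
repeats for the grid and sweep, 500–2000 trees — are the package's
desk-scale defaults; they keep a full verification run in the minutes
range while leaving the protocol shape (stratified 8:2, five-row grid,
nine-fraction sweep) intact. A study-scale run simply raises `repeats`.

## Limitations

Single-fruit, light-background photographs only; no illumination
correction beyond HSI; exactly one Gabor filter per channel (no
multi-scale bank); only the random forest classifier ships, though the
split/evaluate machinery accepts any model wrapped like `train_rf()`.
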