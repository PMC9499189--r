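---
title: "Rotation- and scale-invariant brain MRI tumor classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation- and scale-invariant brain MRI tumor classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lptbrain)
```

## The problem

A classifier trained on axial brain MR slices typically collapses when
the test image arrives rotated or rescaled: gray-level co-occurrence
(GLCM) statistics and wavelet sub-band energies are defined on the pixel
lattice and move with it. `lptbrain` implements a classification
pipeline whose feature extractor is built around the **log-polar
transform (LPT)**, a resampling under which rotation about the center
becomes a circular shift of the angle axis and uniform scaling becomes a
translation of the log-radius axis. Downstream statistics that are
(approximately) invariant to such shifts then inherit rotation and scale
tolerance.

The pipeline is: pre-process (grayscale, resize, median denoise) →
K-means segmentation of the candidate lesion → log-polar and/or wavelet
mapping → a fixed 13-dimensional feature vector → kernel SVM; or,
alternatively, a small convolutional network applied to the log-polar
image. Everything is exercised on a built-in synthetic brain phantom
generator, so the full pipeline is testable without patient data.

## Log-polar transform

A pixel at Cartesian offset $(x - x_c, y - y_c)$ from the chosen center
maps to $(\rho, \theta)$ with $\rho = \log\sqrt{(x-x_c)^2 + (y-y_c)^2}$
and $\theta = \operatorname{atan2}(y-y_c,\, x-x_c)$ wrapped to
$[0, 2\pi)$; the inverse is $x = e^{\rho}\cos\theta$,
$y = e^{\rho}\sin\theta$. `lpt()` samples an $M \times N$ grid —
$\rho$ uniform on $[\log r_{\min}, \log r_{\max}]$ down the rows,
$\theta$ uniform on $[0, 2\pi)$ across the columns — by bilinear
interpolation.

Conventions that matter and are frozen (tests depend on them):

* natural logarithm (forced by the $e^{\rho}$ inverse);
* $\theta$ measured from the $+x$ axis with the image $y$ axis pointing
  down (row index grows downward), so a rotation by $\Delta$ degrees
  equals a **right** circular column shift by $N\Delta/360$ columns;
* scaling by $\alpha$ shifts rows by $\log(\alpha)/\Delta\rho$ bins,
  $\Delta\rho = (\log r_{\max} - \log r_{\min})/(M-1)$;
* defaults $M = N = 64$, $r_{\min} = 1$ px, $r_{\max} = \min(H, W)/2$,
  center = geometric image center; out-of-field samples are filled with
  0 (a `"nearest"` fill is available).

The LPT is deliberately **not** translation invariant: translating
content while keeping the center fixed changes every sample
(`translate_sensitivity()` quantifies this). The pipeline therefore
re-centers before transforming. Two rules are provided: the image
intensity centroid, and — the pipeline default — the centroid of the
K-means tumor mask (`lpt_center = "lesion"`). Lesion centering has two
virtues: the dense small-$\rho$ part of the log-polar grid lands on the
diagnostically informative region, and because the segmentation tracks
the lesion wherever a rotation/scaling moves it, the whole-image
distortion still reduces to (column, row) shifts of the lesion-centered
log-polar view.

## Wavelet decomposition

`dwt2()` is a separable one-level 2-D DWT: filter rows and columns with
an orthonormal analysis pair (low-pass $h$, high-pass
$g_m = (-1)^m h_{L-1-m}$) and decimate by 2, giving the approximation
LL and the detail LH/HL/HH sub-bands; `wavedec2()` cascades on LL.
Haar is the default (simplest orthonormal filter, exact rational test
values); Daubechies-4 (8 taps) is available.

The boundary is handled by **periodization**: the one-level transform is
then an orthogonal matrix, so perfect reconstruction and exact energy
conservation hold to machine precision — properties the test suite
asserts at $10^{-10}$/$10^{-9}$. Symmetric extension was considered and
rejected: with critical decimation it cannot satisfy either property
for filters longer than two taps. Odd lengths are padded by replicating
the final sample, so sub-bands always have $\lceil n/2 \rceil$ entries;
reconstruction is exact for even dimensions (the only case the
perfect-reconstruction guarantee covers).

## The 13-feature vector

`extract_features()` computes, in a fixed order (`feature_names()`):
five GLCM statistics — contrast $\sum (i-j)^2 p_{ij}$, correlation
$\sum (i-\mu_i)(j-\mu_j)p_{ij}/(\sigma_i\sigma_j)$, energy
$\sum p_{ij}^2$, homogeneity $\sum p_{ij}/(1+|i-j|)$, inverse difference
moment $\sum p_{ij}/(1+(i-j)^2)$ — and eight intensity statistics —
mean, standard deviation, Shannon entropy (bits, 256-bin histogram),
RMS, variance, smoothness $1 - 1/(1+\sigma^2)$, kurtosis and skewness
(standardized population moments).

Choices the sources of these definitions leave open, frozen here:

* GLCM quantization: 8 equal-width bins over $[0,1]$; displacements of
  length 1 at 0°, 45°, 90°, 135°, symmetric counting, features averaged
  over the four directions;
* degenerate conventions: correlation of a zero-variance GLCM is 1;
  skewness/kurtosis/entropy of a constant image are 0 — all tested;
* the working image is the level-1 DWT LL band (rescaled to $[0,1]$) of
  the raw or log-polar-mapped image, per the method flags; the "DWT"
  method row uses the raw image, "DWT + LPT" applies the LPT first.

PCA (`fit_pca()`, via `prcomp`) and a FastICA implementation
(`fit_ica()`, symmetric fixed-point iteration with the $\log\cosh$
contrast on PCA-whitened data) are provided as optional reductions of
the 13-column feature matrix; ICA is off by default because a
13-feature vector rarely needs it and its components are only defined
up to permutation and sign. Purely Gaussian inputs are flagged
unidentifiable and returned whitened.

## Segmentation

`segment_image()` clusters pixel intensities (or the a\*b\*
chromaticity plane of CIELAB for RGB inputs, D65 white point, lightness
dropped) with Lloyd's K-means, $k = 3$ by default (background, tissue,
lesion). Initialization is k-means++ under a caller-supplied seed, so
results are reproducible; an emptied cluster is re-seeded at the point
farthest from its center; iteration stops when no center moves more
than $10^{-6}$ (at most 300 passes). The candidate tumor mask is the
cluster of highest mean grayscale intensity restricted to its largest
connected component — the natural rule for T2-like contrast where the
lesion is the brightest structure. On T1-like images (lesion darker
than tissue) the rule degrades gracefully to a bright-tissue mask; the
mask is an artifact for inspection and lesion centering, not a hard
gate, and a degenerate segmentation yields an empty mask plus a
warning rather than an error.

## Classifiers

**Kernel SVM.** `kernel_matrix()` implements the four kernels — linear
$x \cdot y$, RBF $\exp(-\gamma\lVert x-y\rVert^2)$, polynomial
$(x \cdot y + c_0)^d$, and quadratic (the $d = 2$ polynomial). Features
are z-scored with training-set statistics first (without this the RBF
kernel collapses, since raw features span four orders of magnitude).
Defaults: $\gamma = 1/(d \cdot \overline{\operatorname{var}}(X))$,
$d = 3$, $c_0 = 1$, $C = 1$. The soft-margin dual is solved by
kernlab's SMO on the precomputed kernel matrix; support vectors, dual
coefficients and bias are stored so the decision function is exactly
reproducible.

**CNN.** `build_cnn()`/`train_cnn()` implement a small network: four
valid (no padding, stride 1) 3×3 convolution blocks of 32/32/64/64
filters, each followed by ReLU and 2×2 max-pooling (stride 2), then
dense layers of 256 and 512 ReLU units, a third 512-unit ReLU layer
with dropout 0.5, and a 2-way softmax; input is 224×224×3 (grayscale
phantoms are replicated across channels). Training is minibatch RMSprop
(decay 0.9, $\epsilon = 10^{-8}$) at learning rate $10^{-5}$ with batch
size 10 and categorical cross-entropy. Convolution is im2col plus a
BLAS matrix product (C++ kernels under `src/`); backpropagation is
verified against numerical gradients in the test suite. All randomness
— He-initialization, shuffling, dropout — is driven by explicit seeds,
and per-epoch loss/accuracy (evaluated with dropout off) are recorded;
training can stop early once training accuracy reaches 100%. Filter
counts and kernel sizes are configurable; the dense widths, dropout
rate, optimizer, learning rate and batch size above are the method's
stated operating point.

## The phantom generator

`make_phantom()` renders a deterministic (spec, seed) → image mapping:
an elliptical brain with a dark cortical-bone rim, smooth tissue
texture (Gaussian random field, blur scale 12/256 of the image side),
paired dark ventricles; optionally a lesion whose boundary is a radial
low-order Fourier perturbation of a disk scaled by `irregularity`, and
whose interior adds a `heterogeneity`-amplitude random field at
`contrast_delta` (default 0.3) relative to tissue — brighter for
T2-like images, darker for T1-like. Light global smoothing (σ = 1 px)
and additive Gaussian noise (σ = 0.02) finish the image. Class
conventions: benign lesions have irregularity and heterogeneity ≤ 0.2;
malignant ≥ 0.5 in at least one; normals have no lesion. Dataset
presets draw benign parameters uniformly from [0.02, 0.2] and malignant
from [0.5, 0.9] × [0.4, 0.8], which makes malignant phantoms measurably
higher in GLCM contrast and lower in homogeneity than matched benign
ones — the property that makes the classification task learnable, and
a test asserts it.

What the phantom does **not** emulate: MR physics (no Bloch equations,
bias fields, or k-space artifacts), 3-D anatomy, partial-volume
effects, or the seven distinct diseases of real atlases. Passing tests
therefore demonstrate that the pipeline's invariance machinery works as
designed on images with controlled ground truth — not clinical
performance.

`distort()` rotates (±180°) and scales (0.25–1.5×) about the image
center in a single bilinear pass; `make_dataset()` emits
train/validation splits with per-image seeds derived from a master
seed, so a manifest reproduces its dataset bit-identically. Presets
reproduce the published tumor-classification splits: 9/7 train and 2/2
validation (simulated), 18/20 and 4/6 (T2), 13/5 and 4/2 (T1).

## The experiment grid

`run_experiment()` generates a preset's dataset per master seed, fits
each method row ("DWT", "DWT+LPT", optionally "DWT+LPT+CNN" — the CNN
consumes log-polar images and contributes one kernel-independent
column), and evaluates all four kernels on the validation split.
Because the published splits are tiny (2–10 validation images),
single-split accuracies are noise-dominated; the report therefore runs
several master seeds (default 5) and summarizes mean ± sd per
method × kernel.

For the simulated preset the training split is left undistorted and
the validation split is rotated **and** rescaled uniformly over the
full ±180°, 0.25–1.5× ranges. With 16 training images there is no way
to learn the distortion group from data, and a clean reference frame is
what makes the robustness comparison interpretable: the DWT-only
features see a distribution shift at validation time while the
lesion-centered log-polar features largely do not. This is the setting
in which the method-ordering claim (DWT+LPT ≥ DWT on distorted
validation data) is asserted — over ≥ 5 master seeds, as a mean across
kernels, since individual cells on 4 validation images move in 25%
steps. Scale distortion matters here: direction-averaged GLCM
statistics and intensity moments are already nearly rotation-invariant,
so rotation alone separates the methods only weakly, while scaling
strongly degrades the raw-image features and leaves the log-polar path
(where scaling is a row shift) largely intact.

## Numerical choices and problem sizes

* Bilinear sampling treats coordinates within $10^{-9}$ px of the
  border as inside, so grid-exact rotations (±180°, ±90°) do not leak
  fill values.
* Otsu binarization and the 3×3 median filter delegate to EBImage;
  K-means ties (equidistant points) resolve to the lowest cluster
  index; `stats::kmeans` run from the same start is a cross-check in
  the tests, not the implementation.
* Phantoms are 256×256 in the experiment presets (smaller sizes are
  used in unit tests where only mechanics are exercised); the
  log-polar grid is 64×64; the CNN sanity runs train 20 phantoms with
  early stopping, which typically reaches 100% training accuracy in
  30–60 epochs.
* FastICA runs at most 200 fixed-point iterations at tolerance
  $10^{-6}$ and warns (returning the partial result) if it fails to
  converge.

## Known limitations

* The T1-like path inverts lesion contrast, so the brightest-cluster
  segmentation rule does not isolate T1 lesions; lesion centering falls
  back to intensity centroids there.
* Log-polar sampling discards everything outside $r_{\max}$ and
  oversamples the immediate neighborhood of the center; a poor center
  estimate (failed segmentation) degrades the invariance benefit.
* The CNN is a CPU implementation intended for the small datasets the
  pipeline targets; it makes no attempt at GPU-scale throughput.
* Accuracy numbers produced by the experiment grid quantify behavior on
  synthetic phantoms only and are not comparable to results on clinical
  atlas data.
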