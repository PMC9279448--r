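---
title: "Vascular fractal dimension as a retinal image quality score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular fractal dimension as a retinal image quality score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinafd)
```

## The idea

Gradability of a color fundus photograph is, to a first approximation, a
question about how much of the retinal vasculature is visible. A sharp,
evenly illuminated retina shows a rich branching vessel tree; defocus,
an overexposure veil, artefacts or a cropped field of view all destroy
fine vessels first and large ones later. The box-counting fractal
dimension (FD) of a binary vessel map summarizes that visibility in one
number on a continuous scale: a single pixel has dimension 0, an
isolated vessel segment about 1, and a dense vascular tree fills the
plane ever more tightly as its FD approaches 2. In practice, whole-field
vessel maps of high-quality retinas score roughly 1.60–1.70, while
degraded images fall off steeply, so the FD behaves as a quality score
in \[0, 1.7\] with an interpretable rejection band: images below an FD
threshold chosen in \[1.45, 1.50\] are treated as ungradable, and a
stricter cutoff near 1.60 separates "good" from merely "usable".
Because the score is computed from a vessel segmentation the decision is
explainable — the segmentation itself shows *why* an image was rejected.

The pipeline is:

1. **Standardize** (`standardize()`): detect the circular field of view
   (FOV), crop its square bounding box (padding clipped circular
   segments with black), and resize to a fixed side (default 1024), so
   every image enters the measurement with the same geometry.
2. **Segment** (`segment()`): produce a vessel probability map, either
   with a trainable encoder–decoder network or with a weights-free
   multiscale Hessian vesselness filter.
3. **Binarize** (`binarize()`, threshold 0.5) and **measure**
   (`fd_of_mask()`): box-count the binary map and fit the log–log slope.
4. **Classify** (`classify_binary()` / `classify_multiclass()`):
   threshold the FD on the continuous quality scale.

`assess()` composes the four stages and returns a structured report.

## Box counting and the FD estimator

For box size $\varepsilon$ an evenly spaced grid anchored at the
top-left corner is overlaid on the mask and $N(\varepsilon)$ counts the
cells containing at least one vessel pixel. The dimension is the
exponent of the power law $N(\varepsilon) \propto \varepsilon^{-FD}$,
estimated by unweighted ordinary least squares of $\log N(\varepsilon)$
on $\log 1/\varepsilon$ over all sizes with $N > 0$; the fit $R^2$ is
reported as a diagnostic. The default ladder is powers of two from 2 to
half the image side — a deterministic, standard choice; no grid-offset
averaging is performed. An empty mask (or fewer than two usable sizes)
yields `NaN`, which the quality stage maps to the lowest class, because
"no measurable vessels" is the strongest possible rejection signal.

Two numerical caveats are worth knowing and are deliberate:

* **Finite-size crossover.** Compact solid objects that do not fill the
  frame read slightly below their asymptotic dimension: a filled disc of
  radius 400 on a $1024^2$ grid measures ≈ 1.86 rather than 2.00,
  because the boxes of size ≥ 256 saturate their coarse grids while the
  disc covers only half the square. This is a property of finite-range
  box counting itself (the filled *square* measures exactly 2.000 and
  the Sierpinski triangle exactly 1.585 on the same ladder). Shortening
  the ladder would push solid objects toward 2 but would detach the
  vessel-FD scale from the 0–1.7 band the thresholds are calibrated to,
  so the full ladder is kept.
* **Non-monotone slope under removal.** Deleting vessel pixels can only
  lower every box count (a subset property the tests check exactly), but
  the fitted *slope* of the remainder is not guaranteed to drop: removing
  a sparse, locally one-dimensional peripheral wedge occasionally raises
  the OLS slope by a few thousandths. Removing any field that carries
  substantial vasculature lowers the FD clearly.

## Retinal field geometry

For field-wise analyses the FOV is partitioned into six fields: the
optic disc (OD), the macula M — a disc whose radius is $0.6\,d$ where
$d$ is the OD-to-macula center distance — and four quadrants (nasal,
superior, temporal, inferior) bounded by the two 45° diagonals through
the macula center, with "nasal" on the side facing the OD. The six
masks are pairwise disjoint and tile the FOV exactly;
`fd_with_field_removed()` zeroes one field and re-estimates the FD. The
field geometry is supplied by the caller (or by the phantom generator);
no automatic OD/macula localization is attempted.

## Segmentation backends

**Encoder–decoder network.** The trainable backend is a U-Net-style
fully convolutional network: five encoding blocks (each two 3×3
convolutions with batch normalization and ReLU, then 2×2 max-pooling)
with output channels 32, 64, 128, 256, 512; five decoding blocks (2×
nearest-neighbor upsampling, concatenation with the mirrored encoder
feature, two 3×3 conv + BN + ReLU) with channels 512, 256, 128, 64, 32;
and a 1×1 convolution with sigmoid. "Same" padding keeps the spatial
size, so the input side must only be divisible by $2^5$. Training
minimizes the mean pixelwise binary cross-entropy
$L = \frac{1}{MN}\sum -y\log p - (1-y)\log(1-p)$ (predictions clipped
at $10^{-7}$ in the standalone `bce_loss()`; the training path uses the
numerically stable logit form) with Adam at initial learning rate
2·10⁻⁴, default 6 epochs, deterministic under the config seed. The
mirrored channel lists imply skip connections, and concatenation skips
are the field-standard reading, so they are included. The network is
implemented directly on base-R arrays (im2col convolutions running as
BLAS matrix products), which trains reduced configurations — side 64,
channels 8…128 — in seconds on one CPU; full-scale training on a
clinical vessel dataset is out of scope here, so no pretrained weights
ship with the package. Training pairs can be expanded with `augment()`
(random rotations and flips, nearest-neighbor for masks so they stay
binary, every generated pair recording its source and transform).

**Vesselness filter.** The default, weights-free backend is a
multiscale Hessian ridge filter on the inverted green channel (the
highest-contrast channel for vessels): at scales 1, 2, 4, 8 px (scaled
with image side), the scale-normalized Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$ give the Frangi-style response
$\exp(-R_b^2/2\beta^2)\,(1 - e^{-S^2/2c^2})$ with $R_b = \lambda_1/
\lambda_2$, $\beta = 0.5$, zeroed where $\lambda_2 > 0$, maximized over
scales and restricted to the FOV (with a rim margin of twice the largest
scale, since the black exterior is one giant artificial edge). The
structure-magnitude scale $c = 0.035$ is *fixed* in absolute intensity
units rather than adapted per image. This is intentional and load
bearing: per-image normalization would rescale a washed-out image's weak
ridges back to full strength and hide exactly the contrast loss a
quality metric must see. With a fixed scale, blur and overexposure
produce genuinely weaker probabilities, fewer binarized vessel pixels,
and a lower FD.

## Quality thresholds

`quality_thresholds()` defaults to reject below 1.50 and good at or
above 1.60, with class boundaries belonging to the upper class and `NaN`
mapping to Reject. The rejection default sits at the top of the
recommended \[1.45, 1.50\] band — the conservative end for screening,
where a false accept (an ungradable image passed downstream) is costlier
than a false reject. Deployments with gentler cameras or quality
standards should move within the band; the decision rule is monotone in
the FD and in both thresholds, so threshold sweeps behave predictably.

## The evaluation toolkit

`confusion_matrix()` uses the screening convention positive =
sufficient quality; `rates()` computes TPR = TP/(TP+FN), FPR =
FP/(FP+TN), precision, recall (≡ TPR) and FNR. `roc_curve()` and
`pr_curve()` place one operating point at every distinct score with the
rule score ≥ threshold → positive and integrate by trapezoid; the ROC
AUC then equals the Mann–Whitney pairwise-win probability exactly (ties
½), which the tests verify against an exhaustive oracle.
`optimal_cutoff()` maximizes Youden's J on ROC curves and F1 on PR
curves (the standard choices; ties break toward the stricter threshold).
`group_stats()` reports t-based 95% confidence intervals and a Welch
two-sample t-test with significance declared at p < 0.001 — Welch
because equal variances are not defensible across quality groups, and
t-based intervals because group sizes in practice range from tens to
thousands.

## The phantom generator and what it does (not) show

`generate_vessel_tree()` grows `n_roots` recursive binary trees from
the FOV boundary toward the center; stroke width tapers with branching
generation. Every random draw is a counter-based hash of (seed, node
index), so output is byte-reproducible and a deeper tree is a pixel
superset of a shallower one — which makes box-count monotonicity in
depth exactly testable. `render_phantom()` wraps the tree in an
orange-hued background disc with mild radial shading and smooth seeded
texture, a bright OD disc one third of a side nasal of the central
macula, and an exactly black exterior, returning the image, the
ground-truth mask and the matching field geometry. `degrade()` applies
parameterized quality failures (blur; an overexposure veil growing from
the periphery, the classic "milky-white layer"; a lateral illumination
ramp; FOV cropping; vessel-contrast thinning), with severity 0 the exact
identity.

Defaults were fixed once, as the package's study conditions: depth 9,
4 roots, branch angle 40°, length ratio 0.72, initial width 5 px, taper
0.78, rendered at side 512 for tests (the FD of a fixture is stable to
< 0.05 between 512² and 1024², which the suite checks). Under these
defaults the ground-truth trees measure FD ≈ 1.64–1.66, pristine
phantoms pass the pipeline into the good band (≥ 1.60), and severity-1
overexposure lands well below 1.45 — i.e. the recommended thresholds
are exercisable end to end on synthetic data alone.

What passing on phantoms does **not** show: phantoms have no lesions,
no media opacities, no camera vignetting or JPEG artefacts, vessel
contrast is spatially uniform, and — unlike a real retina, where
vessels radiate from the OD and spare the fovea — tree density here
peaks centrally. Results on phantoms validate the *machinery*
(geometry, estimator, monotone response to degradations), not clinical
operating points; thresholds for real deployments must come from real
labeled data.

## Problem sizes and runtime choices

The test suite runs known-fractal fixtures at 1024², phantom studies at
side 512 (50 phantoms for the degradation sweep, 20 for field-removal
properties), box-count oracle comparisons on 200 random 64² masks, and
network training at side 64 (8 pairs, 2 epochs, 3 seeds) — sizes at
which the whole suite completes in minutes on one CPU while still
exercising every stage at realistic geometry. The acceptance script
mirrors these conditions with 20 phantoms per run.

## Known limitations

* FD is blind to *which* vessels are visible: an image missing the OD
  but showing crisp macular vessels can score above threshold (the
  field-definition failure mode), and advanced retinopathy with
  genuinely sparse vasculature scores low despite good optics. Both are
  inherent to a single global vascular score; OD localization and
  DR-grade-aware thresholds are the natural mitigations and are out of
  scope.
* The vesselness backend's fixed contrast scale makes it sensitive to
  global gain changes by design; images from cameras with very different
  exposure conventions should be compared only after standardization.
* The box-count estimator carries the finite-size effects described
  above; FD values are comparable across images measured at the same
  side and ladder, which the standardization stage enforces.
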