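---
title: "Reduced-SIFT photo-identification of dorsal fins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-SIFT photo-identification of dorsal fins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprint)
```

## The problem

Blue whales are catalogued from photographs of the dorsal fin, whose
outline is stable over an individual's life. Field catalogues group fins
into six shape classes — falcate (sickle-shaped, concave trailing edge),
hooked (curled tip) and triangular (straight edges), each photographed
from the right or the left flank — and assigning a new photograph to its
class is the first, labour-intensive step of photo-identification.
`finprint` implements an automatic classifier for this step: a reduced
Scale Invariant Feature Transform (SIFT) front end, a statistical pruning
rule that discards redundant scale-space samples, a nearest-centroid
("median estimation") classifier over the six classes, and an evaluation
harness reporting specificity, sensitivity, accuracy and ROC/AUC per
class.

Because the photographic catalogue the method was developed against is
not publicly deposited, the package ships a synthetic dorsal-fin
generator with ground truth. All quantitative statements below are
computed by the package's own test suite or by `scripts/acceptance.R`;
none are copied from external sources.

## The feature model

### Scale stack and differences

A grayscale region of interest $I$ (luminance in $[0,1]$) is smoothed
with Gaussians of scale $\sigma_i = \sigma_0 k^{\,i-1}$, $i = 1,\dots,n$:

$$L(x, y, \sigma_i) = G(\sigma_i) * I, \qquad
  D_m = L(\cdot, \sigma_{m+1}) - L(\cdot, \sigma_m),$$

a single-octave difference-of-Gaussians (DoG) stack. Defaults are the
classic $\sigma_0 = 1.6$, $k = \sqrt2$, $n = 5$ levels (4 differences).
We deliberately use a single octave — no downsampling pyramid — so that
all difference rasters share one shape and the pooled statistics below
are well defined. Convolution uses replicate padding, implemented as
exact separable clamped-index convolution so that the result agrees with
a direct double-loop convolution to machine precision (this equality is a
tested contract, which is why the package does not delegate to an
FFT-based filter).

### Statistical scale pruning

The package's distinguishing step prunes the DoG stack with a
standard-deviation threshold. With $\bar D$ the elementwise mean over the
$m$ difference rasters, the threshold is the pooled population standard
deviation

$$\sigma_{D} = \sqrt{\frac{\sum_m \sum_{x,y} (D_m(x,y) - \bar D(x,y))^2}
                          {n_{\text{levels}} \cdot n_{\text{pixels}}}},$$

and a retention mask limits the subsequent extremum search. Three
readings of the retention inequality are implemented
(`reduce_mode`):

* `signed_le` (default): retain $D_m(x,y) \le \sigma_D$ — the literal
  inequality;
* `abs_le`: retain $|D_m(x,y)| \le \sigma_D$;
* `abs_gt`: retain $|D_m(x,y)| > \sigma_D$ — discard sub-threshold
  samples as redundant.

These are kept separate because the published rule is ambiguous: the
formula says "retain $\le$", while the stated purpose (remove redundant
samples, keep the significant contour points) implies "discard $\le$".
The ambiguity is not academic. Under `abs_le` every retained sample has
magnitude below $\sigma_D$, which on our imagery is far below the
keypoint contrast threshold (0.03), so every candidate is subsequently
rejected and no descriptors exist at all; `abs_le` is therefore unusable
as a pipeline mode, though it remains available and unit-tested as the
literal reading. `abs_gt` is the magnitude reading that achieves the
stated purpose: on the synthetic study set it retains about 26% of the
scale-space samples while leaving the final descriptor set — and hence
end-to-end accuracy — exactly unchanged, because the samples it removes
are precisely those the contrast test would reject anyway. The default
remains the literal `signed_le`.

Per-level pooling of the threshold (one $\sigma_{D_m}$ per difference
level) is available via `pooling = "per_level"`.

### Keypoints, orientations, descriptors

Candidates are strict extrema over the 26-neighbour scale-space
neighbourhood, restricted to retained samples and excluding a border
margin (`edge_exclusion`, default 4 px). Each candidate is refined by the
standard quadratic fit $\hat z = -H^{-1}\nabla D$ with finite-difference
derivatives in $(x, y, \sigma)$, iterating to the neighbouring sample
when an offset exceeds 0.5, and rejected if unconverged, out of bounds,
singular, or below the interpolated contrast threshold (default 0.03 on
$[0,1]$ luminance). A principal-curvature (edge response) filter is
implemented but off by default: on silhouette imagery virtually every
keypoint lies on the contour, and enabling the filter (threshold 10)
empties the keypoint set — a measured property of this image class, not a
defect of the filter.

Gradient fields use two-pixel central differences,
$M = \sqrt{(L_{x+1}-L_{x-1})^2 + (L_{y+1}-L_{y-1})^2}$ and
$\theta = \operatorname{atan2}(L_{y+1}-L_{y-1},\, L_{x+1}-L_{x-1})$,
so a unit-slope ramp has interior magnitude 2. The two-argument
arctangent is used so orientations cover the full circle; a one-argument
arctangent would fold opposite gradients together and halve the
orientation histogram's expressiveness.

Orientation assignment builds a magnitude-weighted, Gaussian-weighted
(window scale $1.5\sigma$) histogram with 36 bins; under the default
`peak80` rule every bin reaching 80% of the maximum spawns one oriented
keypoint copy at that bin's centre angle. A `literal_mean` mode
thresholds bins at 0.8 times the plain mean of the raw window angles;
this mixes units (an angle average against histogram mass) and is kept
only as a faithful alternative reading, with no claim of being sensible.

Descriptors are the classic 128-vector: a $16\times16$ sample grid
(spacing equal to the keypoint scale), rotated by minus the keypoint
orientation, accumulated into $4\times4$ spatial cells $\times$ 8
orientation bins with trilinear interpolation, Gaussian-weighted with
$\sigma_G$ equal to half the window width (`sigma_g_mode =
"half_window"`; `"half_scale"` uses half the keypoint scale instead).
Vectors are L2-normalized, clamped at 0.2, and renormalized once. The
single clamp-renormalize is the field's standard; note it can leave
entries marginally above 0.2 after the final renormalization, and a
descriptor concentrated in fewer than 25 bins cannot satisfy a strict
0.2 cap and unit norm simultaneously.

## The classifier

Training pools all descriptors of all training images of class $j$ and
aggregates them elementwise into one centroid per class; the default
aggregator is the mean (the defining formula averages), with the
elementwise median available under the scheme's historical name. The
matching statistic for a sample image with descriptors $\{d\}$ is

$$\text{dist}(j) = \sum_{d} \lVert d - c_j \rVert_2^2,$$

and the prediction is the argmin over the six classes, ties resolving to
the earliest class in declared order. With the mean aggregator and one
training image per class this reduces exactly to a nearest-exemplar
(minimum-distance) classifier, which is one of the published baselines; a
K-nearest-neighbour baseline over chamfer-style image distances
(`knnClassify`, default $K=3$) is also provided.

## Evaluation

Image-level six-class evaluation is one-vs-rest: for each class,
confusion counts over predicted labels give Sp $=$ TN/(TN+FP), Se $=$
TP/(TP+FN) and Acc $=$ (TP+TN)/total, with undefined ratios reported as
`NA` rather than silently zero. The cross-class spread statistic is the
population standard deviation of the six per-class accuracies.

Per-class ROC curves score each test image by the **decision margin**:
the smallest distance to any other class minus the distance to the class
under test. This is a deliberate design decision. The naive score
(minus the class distance) is confounded by the per-image descriptor
count, which inflates every class's aggregate distance alike; measured on
the synthetic study set it produces AUC values below chance for classes
the classifier predicts correctly. The margin is the unique score whose
threshold at zero reproduces the classifier's own decision rule, making
the ROC a faithful generalization of the reported Sp/Se/Acc. The naive
score remains available (`rocScore = "neg_distance"`).

AUC is computed by threshold sweep with tie grouping and trapezoidal
integration, and is cross-checked in the test suite against both an
all-pairs counting oracle and an independent ROC implementation.

## The synthetic generator

`generateFin()` renders a fin silhouette (luminance 0.25 on background
0.75) from cubic Bézier outlines parameterized by a single `tipCurl`
value with class-specific bands — triangular $[0, 0.15]$, falcate
$[0.35, 0.6]$, hooked $[0.75, 1.0]$ — plus base width, rotation and
scale, anti-aliased by $3\times3$ supersampling, composited over a flat
or sea-texture background (low-frequency sinusoid mixture), and overlaid
with zero-mean Gaussian noise. Every render is fully determined by its
integer seed; dataset seeds are derived arithmetically
(`baseSeed * 10000 + index`) so no global random state is consumed.
Left-flank classes are produced by rendering the mirrored right-flank
geometry and flipping the raster, noise field included, so mirror pairs
are exact horizontal flips by construction. The ground-truth contour
mask marks the rendered outline before noise.

The study protocol used by the acceptance tests and
`scripts/acceptance.R` is: 96 × 96 rasters; 20 training and 20 test
images per class (240 images total, stratified split); geometric jitter
on (rotation ±10°, scale 0.85–1.2, tip curl uniform within the class
band, base width 0.40–0.50 of the frame); noise sigma 0.02. The 96-pixel
frame keeps the full protocol — three complete extraction passes for the
pruning comparison — to a few minutes on one CPU while leaving the fin
roughly 70 px tall, comfortably above the coarsest descriptor scale.

What the generator does **not** emulate: photographic texture and
pigmentation, water and splash occlusion, perspective foreshortening,
exposure variation, and the fuzzy fin/sea boundary of backlit
photographs. Passing the synthetic protocol therefore demonstrates that
the pipeline's geometry, statistics and code paths are correct and that
the method can separate clean shape classes; it does not predict field
accuracy on real photographs.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open, `(x = column, y = row)` everywhere.
* Replicate padding for all convolutions and gradients; constant images
  propagate to empty keypoint sets, not errors.
* The quadratic localization rejects candidates with singular Hessians
  (`solve` failure) rather than regularizing, and bounds offsets to the
  stack interior.
* Orientation histograms with zero total weight drop the keypoint;
  all-zero descriptor windows reject the descriptor.
* Classifier ties resolve deterministically by declared class order;
  `which.min` order is pinned by a unit test.
* Undefined Sp/Se (empty denominator) are `NA`, never 0, preventing
  inflated macro averages on degenerate class splits.
* Config hashes are FNV-1a over a canonically sorted serialization, so
  field order cannot change a hash; models refuse descriptors extracted
  under a different configuration.

## Known limitations

* The pooled-centroid classifier collapses each image to its mean
  descriptor. On rotation-normalized descriptors of smooth silhouettes
  the between-class to within-class separation ratio under the jittered
  protocol is only slightly above 1, which caps attainable per-class
  AUC and clean-sample recall well below perfect; the K-NN baseline,
  which compares descriptor sets rather than means, is measurably
  stronger on the same features. This is a property of the method being
  implemented, reproduced faithfully.
* Single-octave scale coverage means very large or very small fins in
  the frame shift features across levels rather than octaves; the
  generator's scale jitter stays within that envelope.
* The segmentation stand-in (gradient threshold + largest 8-connected
  component) is intentionally simple; its default threshold (0.25) is
  calibrated to the generator's fin/background contrast of 0.5 and will
  need adjustment for photographs.
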