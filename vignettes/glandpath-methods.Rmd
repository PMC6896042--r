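---
title: "Gland segmentation and hierarchical classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland segmentation and hierarchical classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glandpath analyses hematoxylin-and-eosin (H&E) stained colon histology.
Its premise is morphological: a healthy colonic gland (crypt) is a ring-like
unit — a white central lumen, surrounded by pale epithelial cytoplasm,
bounded by a ring of purple-stained basal nuclei, embedded in pink stroma —
and malignancy progressively destroys this architecture. The package turns
that premise into a pipeline: colour clustering isolates the three tissue
components, a multi-step geometric procedure reassembles them into glands,
radiomic features quantify texture and gland morphology at three scales,
and a stacked SVM ensemble classifies images as normal versus malignant and
by grade.

This vignette explains each stage's model, its tunable parameters, the
numerical choices behind them, and what the synthetic phantom — the
package's test bed — does and does not establish about real tissue.

## 1. Tissue clustering

Pixels are partitioned by K-means (k = 3, ten restarts, fixed seed) on raw
RGB vectors. Semantic names are attached to the *centroids*, not the
cluster indices, so the labelling is invariant to K-means ordering: the
most luminous centroid is WHITE (lumen and cytoplasm), the darkest is
PURPLE (hematoxylin-stained chromatin), the remainder is PINK (eosin-stained
stroma). This stain-motivated ordering is robust for any reasonably stained
H&E image; it is the package's own rule, since stain chemistry fixes only
the extremes.

Contrast enhancement (`enhance_contrast()`) is a per-channel linear
stretch. The default maps the channel minimum/maximum to [0, 255], which is
exactly idempotent and leaves constant channels untouched; robust
percentile bounds (e.g. 1st–99th) are available through the `lower`/`upper`
arguments for images with hot pixels. The stretch is applied before
*clustering*, where it only sharpens colour separation. It is deliberately
**not** applied before texture extraction (see §3).

Cluster cleanup uses a disk erosion of radius 1 (at radius 1 the discrete
disk equals a 3×3 box). Erosion detaches thin bridges between adjacent
nuclei and removes single-pixel noise at the cost of about one boundary
pixel per object, which the later region growth restores.

## 2. Gland segmentation

### 2.1 Candidate objects

Connected components of the eroded WHITE and PURPLE masks become candidate
objects, each summarised by a moment-fit ellipse: the centroid and second
central moments (with the 1/12 unit-pixel variance correction) give the
semi-axes (`2*sqrt(eigenvalue)`) and the orientation, in closed form and
deterministically. On graded (area-coverage) rasters the moments are
pixel-weighted, which preserves subpixel boundary information; on the
binary cluster masks the fit degrades gracefully. Components below
`min_area` (default 15 px for nuclei, 60 px for white candidates — a lumen
or cytoplasm fragment is larger than a single nucleus) are dropped as
rasterisation specks. Both thresholds assume the reference scale of the
phantom (nuclei of radius ≈ 4 px); rescale them with your magnification.

### 2.2 Discriminating true components from false positives

Real tissue scatters nucleus-like and pale objects through the stroma. Each
candidate is described by its area, compactness, mean distance to its five
nearest cohort neighbours, and the tissue composition of a *context
window*; Ward-linkage agglomerative clustering on z-scored features, cut at
two clusters, separates gland-associated from stromal objects. The cluster
kept as TRUE is chosen by stain context: true nuclei sit against white
lumen/cytoplasm, true white objects are ringed by purple nuclei.

Two design choices matter here:

* **Context window.** The default window is a morphological shell — pixels
  within `shell_width` (6 px) of the object but not adjacent to it. A shell
  is scale-free: the same window width works for a 30 px nucleus and a
  1000 px cavity. The co-centric-ellipse annulus (four nested scaled copies
  of the fitted ellipse, scales 1–2.5) is implemented and available
  (`context = "cocentric"`), but for large objects most of a proportional
  annulus is distant stroma, which dilutes the signal; the shell is the
  default for that reason. The co-centric overlays share the object's
  orientation so that the masks are strictly nested (rotated variants are
  available but cannot guarantee nesting for eccentric ellipses, and are
  flagged).
* **Homogeneity guards.** An unconditional 2-cut *must* split, even a
  cohort that is entirely true objects (a clean image has no false
  positives). `segment_image()` therefore accepts a split only when it is
  supported: the mean silhouette of the 2-cut must exceed 0.35, and a
  cluster is only marked FALSE when its mean context ratio falls below an
  absolute floor (0.1 — stromal false positives have near-zero gland
  context, true components always carry some). Lumen detection analogously
  requires the two clusters' mean areas to differ by at least a factor of 4
  before calling the smaller one cytoplasm: lumina legitimately vary 2–3×
  in area, fragments are an order of magnitude smaller. With the guards
  disabled (their faithful-2-cut defaults), the operations behave as pure
  clustering cuts, which is what the unit tests of the cut itself use.

### 2.3 Lumen detection, region growth, boundary nuclei

True white objects are split into LUMEN and CYTOPLASM by a further 2-cut on
(area, compactness, neighbour distance); the larger-area cluster is the
lumen class, with exact ties resolved towards higher compactness.

Each lumen seeds an iterated dilation (3×3 disk) that stops at the first
iteration adding no new nucleus pixels. Iterations that add no nuclei are
tolerated only before first contact with any nucleus — the region must be
allowed to travel across the gap to the nucleus ring — and termination is
guaranteed by the image bound. One further manual dilation after the stop
adds no nucleus pixel (a fixed-point property the tests assert). Growth is
restricted to the non-stroma support (WHITE ∪ PURPLE pixels): dilation is
isotropic, and without the restriction the grown region would overshoot
into stroma by roughly one nucleus diameter all around, biasing every
downstream area feature. On images where stain noise corrupts the support
this restriction can be disabled (`restrict_to_tissue = FALSE`).

Rays are cast from the lumen centroid through every boundary pixel of the
grown region out to the image border (sampling step 0.5 px); the first
nucleus each ray intersects becomes a candidate boundary nucleus. Each
candidate is then described by its five sorted nearest-neighbour distances
among candidates; a 2-cut flags distance outliers (nuclei of *other* glands
caught by stray rays), keeping the cluster with the smaller mean neighbour
distance. Besides the silhouette guard, a raw-scale guard skips the cut
entirely when the relative spread of mean neighbour distances is below
0.25: z-scoring a near-constant feature would amplify rasterisation noise
into a spurious split of a perfectly regular ring.

The gland is completed by dilating the internal region until every
boundary-nucleus pixel is covered. Two lumina occasionally grow into
essentially the same territory (a fragmented cavity produces two white
objects inside one gland); glands whose regions overlap with IoU ≥ 0.5 are
merged, keeping the larger lumen. Genuinely distinct glands, which overlap
at most marginally, are resolved by assigning contested pixels to the
nearer lumen centroid. Glands are labelled in row-major order of their
lumen centroids, making the output independent of discovery order.

## 3. Radiomic features

**Image scale.** Texture is quantified by 11 Haralick features (entropy,
energy, correlation, inverse difference moment, inertia, sum average, sum
entropy, sum variance, difference variance, difference average, difference
entropy) of the spatial gray-level dependence (co-occurrence) matrix at
offset 1 and angles {0°, 45°, 90°, 135°}, 8 gray levels, symmetrised,
normalised, averaged over the four angles. Entropies use the natural
logarithm; levels are indexed from 0. With this angle set the averaged
features are invariant to 90° rotation. Grayscale conversion uses the
luminance weights (0.299, 0.587, 0.114) and quantizes the **absolute**
8-bit range into equal bins: a per-image contrast stretch would make the
bin boundaries image-dependent, so that the same tissue would yield
different co-occurrence statistics depending on what else is in the frame —
a known pitfall of per-image normalisation before co-occurrence analysis.
The stretch therefore defaults off for texture (argument available).

**Gland scale.** From each segmented gland: standard deviations of
epithelial-component and nucleus centroid distances to the lumen centroid
and of their areas; the six component size ratios (each component over the
gland, plus the three pairwise ratios, with unit-denominator guards); and
nine region morphology features (area, compactness, convex area,
eccentricity, Euler number, major/minor axis length, orientation,
perimeter). Compactness is 4π·area/perimeter², with the perimeter measured
as the polygonal length of the traced boundary contour — for a digital disk
this keeps compactness just below the ideal 1. All distances and areas are
in pixels; no magnification correction is applied, and cross-magnification
use requires the caller to rescale (`deliberately` exposed rather than
guessed). Images contribute their 5 largest and 5 smallest glands by area
(ties broken by gland id); images with fewer than 10 glands repeat glands
in area order, and images with none pad with zeros — both flagged — so
every bundle has identical dimensionality, which the classifier requires.

**Patch scale.** The image is tiled into non-overlapping 64 px patches
(border remainders dropped); five random subsets of half the tiles are
drawn per image, the raw SGLD counts of each subset's patches are pooled
per angle, and the same 11 features are computed per subset. Pooling counts
before normalisation (rather than averaging per-patch features) keeps the
estimates well-conditioned for small patches; per-patch averaging remains a
configuration option. Patch defaults are package choices — the tiling scale
is unspecified territory — and give 9 tiles on the 192 px phantom.

## 4. Two-level classification

Level 1 fits one RBF-kernel SVM per feature family: image texture, gland
morphometrics, and one *weak classifier per patch subset*. The weak
classifier with the highest confidence — operationalised as the mean
top-class probability margin on inner validation folds — supplies the patch
probability score (a vote-average over all weak classifiers is available
via `patch_mode = "vote"`). Level 2 stacks the three probability score
vectors into a meta-feature vector and fits linear, RBF and sigmoid SVMs on
it; their majority vote (ties: highest summed probability, then class
order) is the final prediction.

Probability scores are one-vs-rest Platt sigmoids: each binary SVM's
decision values on inner out-of-fold data are calibrated with Platt's
regularised sigmoid fit (smoothed targets, BFGS), and the per-class
sigmoid outputs are normalised to sum to one. This replaces libsvm's
built-in probability machinery, whose internal random shuffling is not
seedable from R and would break run-to-run determinism; it also pins the
multi-class decomposition to one-vs-rest, which keeps the meta-feature
layout transparent (3 × number of classes). Hyperparameters are
grid-searched on log₂ lattices (default C ∈ 2^{−3..12}, γ ∈ 2^{−9..3} in
steps of 3; a wider 2^{−5..15} × 2^{−15..3} lattice via
`svm_grid(full = TRUE)`) by stratified 3-fold accuracy within the training
data only. The default lattice is sized to the cohort sizes this package
documents (tens of images, tens to hundreds of features).

Leakage control is structural: scaling, grid choice, calibration, weak-
classifier selection and meta-training all happen inside the training
portion of each outer fold. Meta-features for training the level-2 SVMs
come from an internal 5-fold cross-validation of the training portion, so
the meta level never sees resubstitution probabilities. A canary test
asserts the property directly: a feature informative only in held-out data
cannot change predictions. Cross-validation is stratified by class;
`cv_scheme(group_key = ...)` keeps all images of one slide/patient in one
fold, for cohorts where images are subdivisions of larger specimens.

## 5. Evaluation

Segmentation is scored pixelwise against ground truth: sensitivity,
specificity, accuracy, Dice, Jaccard and F-score (for pixel counts the
F-score equals the Dice; both are reported for completeness, and the
identity J = D/(2−D) is asserted property-style). Per-gland scores match
each true gland to the predicted gland of largest overlap. Metrics are
computed per image and averaged; pooled-pixel aggregation is available.

Classification reports accuracy, sensitivity, specificity (macro-averaged
one-vs-rest for three classes; micro available), the Matthews correlation
coefficient in Gorodkin's multi-class generalisation (equal to the usual
binary MCC for two classes), and one-vs-rest ROC/AUC by the trapezoidal
rule over pooled out-of-fold probabilities (cross-checked against pROC in
the test suite).

Feature interpretation uses the two-sided Wilcoxon rank-sum test — exact
null when both groups have ≤ 10 observations without ties, normal
approximation with tie correction otherwise — with Bonferroni correction,
plus tidy boxplot data and linear-SVM weight ranking for selecting the most
discriminative features.

## 6. The phantom: what it emulates, and what it does not

`generate_phantom()` draws H&E-like images with exact ground truth. A gland
is, at deformation 0, a perfect circle: lumen disk (45% of the radius),
epithelial annulus, and a ring of 10 nuclei (radius 4 px) whose centres are
exactly equidistant from the gland centre. Glands (default 3 per 192×192
image, base radius 20–25 px) are placed by rejection sampling with
non-overlap margins; placement failure after bounded restarts is an
explicit error. Colours default to white (235,235,235), pink (230,150,180),
purple (120,60,150) with Gaussian noise of sd 10, and stray stromal nuclei
and pale blobs can be injected (`false_object_rate`), never touching
glands.

The single `deformation` knob (0–1) drives an ordered loss of architecture,
mapped to grades as normal = 0, well = 0.2, moderate = 0.5, poor = 0.8:

* area-preserving elongation of the gland (up to 1.35:1), so ideal glands
  are circles — which is what makes the equidistant-ring property exact —
  and deformed glands are eccentric;
* a low-frequency radial perturbation of the boundary (harmonics 2–4,
  amplitude 18% of the radius at deformation 1), whose mean displacement
  is the generator's internal monotonicity witness;
* inward half-normal radial scatter and angular jitter of the nuclei —
  loss of basal nuclear polarity;
* stromal pockets inside the epithelium (count ∝ deformation², radius
  growing with deformation) — desmoplastic invasion, which carves
  pink-stained holes into the gland territory;
* texture disorder: a smooth random darkening field over the stroma and
  per-nucleus chromatin intensity jitter, both vanishing at deformation 0.

These levers were chosen so that each pipeline stage degrades for the
*mechanistic* reason it would degrade on real tissue: scattered nuclei
stall the region growth early, pockets break the support the growth fills,
texture disorder raises co-occurrence entropy. Sample sizes used in the
verification suite — 20 images per deformation level for segmentation, 30
per class for detection, 20 per class for feature statistics — are the
package's documented study conditions.

What passing on phantoms does **not** show: robustness to stain variation
between laboratories (phantom colours are fixed), to touching or cut
glands (placement forbids overlap), to mucin, goblet cells, inflammation or
tissue folds, or to the extreme gland loss of the poorest differentiation.
Real H&E cohorts remain the only test of those. The phantom's role is to
verify the machinery — exactly, because its ground truth is exact.

## 7. Numerical conventions and degenerate inputs

* Determinism: every stochastic step (placement, K-means, fold assignment,
  subset sampling, SVM calibration folds) derives from an explicit seed;
  identical seeds give identical outputs, across sessions.
* Ties: grid search takes the first optimum in deterministic expansion
  order; lumen-area ties fall back to compactness; vote ties to summed
  probability then class order; gland ordering is row-major by centroid.
* Degenerate inputs fail loudly and specifically: fewer than three colours
  ("degenerate clustering"), identical feature rows ("indiscriminable
  cohort"), single-class training labels, all-zero confusion tables. A
  segmentation that finds no lumina returns an empty result with a
  diagnostic rather than an error, so batch runs continue.
* Division guards: component ratios use unit-denominator floors; constant
  features in Wilcoxon comparisons return p = 1 with a flag; zero-variance
  features are dropped from SVMs with a warning.
* Correlation of a constant texture field is defined as 0 (both marginal
  variances vanish).

## 8. Known limitations

Segmentation accuracy is bounded by the colour separability of the three
tissue classes; heavy stain bleed-through would require stain
deconvolution, which is out of scope. The region-growing step assumes each
gland's lumen is detectable as a white object; glands whose lumen is
collapsed or obliterated are missed by construction. Features carry pixel
units with no magnification normalisation. The patch-subset weak
classifiers share one random tiling per image; spatially stratified
sampling is not implemented. Cohort sizes in the tests are desk-scale:
statements about real-data performance require real cohorts.
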