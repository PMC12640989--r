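---
title: "Methods: feature-combination mapping of fragmented crop plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-combination mapping of fragmented crop plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Ligusticum chuanxiong* (LC) and other high-value medicinal crops are grown on
small, scattered plots interleaved with forest, other vegetation, bare soil and
buildings. Consumer UAVs deliver only three visible bands, and from nadir an LC
bed and a forest canopy are nearly metameric: their RGB statistics overlap, so
per-pixel color classification confuses them. What does separate them is
texture (a manicured bed is far smoother than a canopy) and elevation (a canopy
sits metres above the ground plane, the crop a metre or less). `plotsieve`
operationalises exactly this idea: build a wide feature space from the RGB
orthomosaic and its photogrammetric DEM, screen it down to one representative
per feature family, and quantify how much each family combination buys under
four classifier families.

## The feature space

41 layers are derived from a 3-band 8-bit orthomosaic and a co-registered DEM:

* **12 visible-band color indices (CI)** — GCC, RCC, BCC, GRVI, WI, GLI, VARI,
  EXR, EXG, EXB, CIVE, VDVI, computed pixel-wise on raw digital numbers. The
  excess-red/green/blue family is defined on the chromatic coordinates, e.g.
  EXG = 2·GCC − RCC − BCC; CIVE keeps its published DN-scale constants. Pixels
  where a denominator vanishes (WI with R = G, VARI with G + R = B, chromatic
  ratios on a black pixel) become NoData in that layer rather than infinities:
  masking is auditable, clamping is not, and the affected indices are screened
  out downstream anyway.
* **24 texture layers (GLCM)** — for each band, the eight co-occurrence
  statistics Mean, Variance, Homogeneity, Contrast, Dissimilarity, Entropy,
  Second Moment and Correlation over a 3×3 window, 64 gray levels, displacement
  (0, +1) (the 0° direction at distance 1). The matrix is symmetrised before
  normalisation — the standard Haralick convention — because only the angle is
  conventionally stated, not the directionality. Edge pixels get full windows
  by reflect-101 padding so the texture rasters keep the source geometry.
  Two non-obvious readings are deliberate: the Mean statistic is the
  row-marginal mean Σ i·P(i,j) (with symmetric P this equals both marginal
  means), and Correlation on a zero-variance window (a constant 3×3 patch —
  common at this window size) is defined as 0 and flagged, since the formula is
  0/0 there.
* **4 color components (CS)** — Hue (identical in HSV and HLS, stored once,
  in [0,1)), Light from HLS, Saturation and Value from HSV. Achromatic pixels
  get Hue 0 and Saturation 0.
* **1 DEM layer** — elevation in metres, as produced by the photogrammetric
  reconstruction.

## Screening and combinations

Sample points are read from the single pixel containing them (points carry a
nominal 0.2 m radius as metadata; at 0.10 m/pixel that spans ~2 pixels and no
averaging rule is defined, so none is invented). Screening uses **training
rows only** — it precedes classification and must not touch validation data.

For each feature, class means `Mc` (the LC class) and `Mn` (each other class)
give the interclass difference score

> Dw = |(Mc − Mn) / Mc| · 100 %.

Dw is scale-invariant and undefined when `Mc = 0` (such features are treated
as non-informative). A Pearson correlation matrix over all candidate features
is reported for inspection but deliberately not used to prune beyond the
one-per-category rule below, mirroring the workflow being reproduced.

Representative selection is stated narratively in the source workflow; it is
formalised here as a total, deterministic rule: within each of the CI, GLCM
and CS categories, pick the feature **maximising the minimum Dw** across the
four non-LC classes; ties break by higher mean Dw, then lexicographic name.
Features with any undefined Dw are excluded; the DEM is a category of one.
This rule is consistent with the published picks (VDVI, B-MEA, Hue), which are
the features whose worst-class separation is largest in the published tables.

The 15 feature combinations FC1–FC15 are all non-empty subsets of
{CI, CS, GLCM, DEM} in canonical order (four singletons, six pairs, four
triples, the full set), plus an RGB baseline over the raw bands.

## Classifiers

* **Gaussian maximum likelihood (pixel)** — class-conditional Gaussians with
  sample means/covariances and equal priors; discriminant
  log π − ½log|Σ| − ½·Mahalanobis². Covariances are ridge-regularised
  (ε·trace/d on the diagonal, ε escalated from 1e−8 until Cholesky succeeds)
  so duplicate-row or short training sets stay usable. Ties break to the
  lowest class code, everywhere, for total determinism.
* **SVM (pixel and object)** — radial basis kernel with pinned defaults
  (cost 1, kernel width 1/d on standardised features, one-vs-one voting),
  via `e1071`. Features are standardised by training mean/scale for the SVM
  but not for ML: the Gaussian discriminant is affine-equivariant, the kernel
  is not. The "default specifications" of the proprietary tools the workflow
  originates from are not recoverable, so these pinned values are a declared
  substitute recorded in the configuration, not a reproduction.
* **KNN (object)** — each object takes the majority class of its k nearest
  labelled objects in standardised Euclidean feature space (default k = 1,
  the classic nearest-neighbour object classifier); ties break by the nearest
  single neighbour, then lowest code.

Pixel maps can be cleaned with a majority filter (3×3, one pass by default):
modal label of the clipped neighbourhood, NoData excluded, current label
retained on ties. The filter never invents labels and never increases the
connected-component count.

## Object segmentation

The object pipeline uses bottom-up multiresolution region merging. From
single-pixel regions, the mutually-best-fitting adjacent pair merges while the
fusion cost

> f = (1 − shape)·Δh_color + shape·(compactness·Δh_cmpct + (1 − compactness)·Δh_smooth)

stays below scale², with Δh_color = Σ_L w_L (n_m σ_m − n₁σ₁ − n₂σ₂),
compactness term √n·l and smoothness term n·l/b (l = perimeter, b = bounding
box perimeter). Defaults: shape 0.3, compactness 0.5, unit layer weights,
segmentation on the RGB bands. Sweeps scan live regions in ascending id and
tie-break to the lowest id, so results are deterministic; merged regions keep
the smaller id. The scale parameter is **not transferable across
implementations**: 300 is the conventional default label, while desk-scale
synthetic scenes use scale 25, chosen from the `scale_profile()` local-variance
diagnostic as the knee where objects stay class-pure (object boundaries need
not be learned — only be fine enough that objects are pure; the profile shows
object counts and within-object dispersion across a scale ladder).

Object classification uses per-layer means of the active combination (standard
deviations are computed into the object table but excluded from classification
by default, matching the common nearest-neighbour practice). Dissolving
boundaries simply drops the object partition, keeping classes.

## Evaluation and ranking

Validation points give a confusion matrix (rows = predicted, columns =
reference, LC first; NoData predictions go to a reject tally outside n).
Overall accuracy is the diagonal fraction; the printed summation form of the
OA equation in the source would be identically 1, so the standard diagonal
reading is used. Kappa is chance-corrected agreement; producer accuracy
divides the diagonal by the reference (column) sum, user accuracy by the
prediction (row) sum, F1 is their harmonic mean. The composite score is the
equal-weight mean

> 0.2·(OA + Kappa + PA_LC + UA_LC + F1_LC),

with all five terms as fractions in [0,1] before weighting — published tables
mix percent and unit scales, and converting first is what reproduces the
published FC15 composites (0.91 pixel-ML, 0.93 pixel-SVM) exactly.
`pa_from_f1_ua()` inverts the F1 formula (PA = F1·UA/(2·UA − F1)) so composite
scores can be reconstructed from tables that print F1 and UA but not PA.

Five-fold cross-validation assigns stratified folds to training points; each
fold's model is evaluated both on the held-out fold (diagnostic) and on the
validation split. The validation-split composites are the replicate unit for
ranking — the source never states its replicate unit, and this choice assesses
the full map against verification samples, which is what its tables report.
One-way ANOVA across combinations, then Tukey HSD contrasts against the RGB
baseline, produce the ranking table; combinations significantly above the
baseline (p < 0.05) are starred. When all per-fold scores are identical the
residual variance is zero, the p-values are undefined, and no stars are
awarded.

## The synthetic scene generator

No public imagery accompanies the source workflow, so the generator is a
first-class module that emulates its statistical structure rather than a
stand-in fixture:

* **Metameric preset.** LC and forest share near-identical green RGB means but
  differ in texture correlation length (4 px vs 1 px) and elevation offset
  (1 m vs 10 m). This makes RGB-only classification measurably worse than the
  feature stack — the central claim the test suite must be able to observe.
  The other three classes (other plants, bare land, construction) have
  progressively more distinct colors, realistic for the landscape modelled.
  Published per-class spectral means for the real sites are not available, so
  these signatures cannot be (and are not) calibrated to them; published
  site-level Dw and accuracy values are therefore not reproduction targets.
* **Texture** is white noise smoothed by a Gaussian kernel of width
  `texture_scale`, then re-standardised *within each class region*, so class
  means and spreads are recovered exactly up to 8-bit rounding regardless of
  the spatial autocorrelation. Larger `texture_scale` is smoother, which the
  texture layers pick up monotonically (lower contrast, higher homogeneity).
* **Geometry.** Axis-aligned rectangular plots placed without overlap (LC),
  over a Voronoi mosaic of the background classes — a cheap reproduction of
  scattered, fragmented smallholder plots. Impossible placements error rather
  than silently truncating.
* **Sampling.** Stratified random points at pixel centers of their class with
  a global >3 m pairwise spacing rule (grid-hashed rejection sampling) and a
  0.2 m nominal radius kept as metadata; training points get stratified
  5-fold assignments.
* **Scale.** The published sampling pattern (hundreds of points per class at
  >3 m spacing) needs site-scale extents. A 400×400 grid at the native
  0.10 m/pixel spans only 40 m and cannot hold it, so pipeline-scale scenes
  use 1 m pixels: a 400×400 grid then spans 16 ha — the extent of the real
  sites — and the 3 m rule and published per-class counts (e.g. 700/700/700/
  550/550) apply verbatim. The 0.10 m default remains for resolution-faithful
  small scenes.

What the generator does **not** emulate: sensor radiometry, illumination and
shadow, mixed pixels at plot borders, phenological variation, and georeferencing
error. Passing tests therefore demonstrate that the pipeline's machinery is
correct and that its qualitative claim (feature combinations beat raw RGB when
classes are spectrally confusable) holds on controlled data — not that the
published site-level accuracies transfer to any particular real scene.

## Problem sizes and numerical choices

Default demonstration sizes: 256×256 scenes for the standard pipeline run,
400×400 for the stress-scene comparison, 600×600 (1 m pixels) for the
published sampling pattern; 64 gray levels and 3×3 windows for texture; five
folds throughout. The GLCM slide and the region merging are implemented in
C++ (Rcpp); everything else is vectorised R. Raster I/O uses TIFF with ESRI
world files and JSON sidecars for CRS/NoData/band names; float layers are
packed to the TIFF [0,1] sample range with per-layer offset/scale recorded in
the sidecar (8-bit bands and labels round-trip exactly, floats to the 32-bit
quantisation of their range). Master seeds fan out to stages by a stable
stage-name hash kept below 2³¹.

## Known limitations

* Segmentation-scale equivalence to other software is undefined by
  construction; only within-implementation comparisons are meaningful.
* The Dw score is undefined for features whose LC mean is 0 and unstable when
  it is near 0; such features are excluded from selection rather than patched.
* Object training uses point-in-object label transfer; objects straddling a
  class boundary can be dropped as conflicted, shrinking the training set.
* Composite-score ranking inherits the ANOVA assumption of comparable
  per-fold variances across combinations; with five folds the Tukey contrasts
  are conservative.
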