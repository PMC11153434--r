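---
title: "Consensus-contour PET radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-contour PET radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`conseg` studies a practical question in quantitative PET imaging: when a
tumor is delineated automatically, how much do radiomic features depend on
the segmentation method and on the loose initial mask a reader draws around
the lesion — and does fusing several segmentations into a consensus contour
by majority vote make the features more reproducible? Because clinical
scans with ground truth are rarely available, the package ships a digital
phantom generator with known tumor masks, so robustness (agreement between
masks or among methods) and accuracy (agreement with ground truth) can both
be quantified per feature with intraclass correlation coefficients.

This vignette documents the models, the tunable parameters with their units
and defaults, the numerical choices, and the limits of what the synthetic
experiment can show.

## The phantom model

`generate_suite()` emulates a static thoracic PET acquisition of lung
lesions at clinical scale and resolution:

* **Grid.** 200 × 200 in-plane matrix with 0.41 × 0.41 cm pixels and 32
  slices of 0.50 cm. All distances in the package are centimetres.
* **Scene.** Body background of 1.0 SUV, a large lung-like ellipsoid of
  0.3 SUV around the lesion, and an ellipsoidal tumor. Thirteen cases are
  generated per suite; their target volumes sit on a log-spaced ladder with
  a small seeded jitter so the suite spans roughly 3.45–56.40 cm³ from
  small to large lesions, and baseline tumor uptake is drawn uniformly in
  4.5–8.0 SUV.
* **Intra-tumor heterogeneity.** A seeded Gaussian random field (blurred
  white noise, correlation length 0.8 cm, standardized inside the tumor)
  plus a hot-core radial profile, both multiplied by an amplitude of
  0.6 SUV. Setting the amplitude to zero yields a perfectly uniform lesion,
  which several tests exploit. No anatomical texture law is claimed; the
  field is simply a smooth, reproducible source of within-lesion variation.
* **Hot distractor.** Each case places a 0.7 cm-radius blob of 5.5 SUV one
  centimetre beyond the lesion surface along an in-plane diagonal — the
  region of a bounding-box mask with the most spare room. Its uptake is
  deliberately within the lesion range: a "high uptake area nearby" only
  matters if it can disturb a segmentation, e.g. by corrupting the
  within-mask maximum or bridging into the contour through its
  partial-volume halo.
* **Acquisition.** The activity map is convolved with an isotropic Gaussian
  point-spread function (FWHM 6 mm, typical of clinical PET), degraded with
  scaled Poisson noise (`noisy = s * rpois(blurred / s)`, so the voxel
  variance is `s` times the blurred mean; default `s = 0.08`), and finally
  smoothed with a 4 mm FWHM post-reconstruction Gaussian filter. The
  post-filter matters: reconstructed PET noise is spatially correlated, and
  without it the within-mask maximum is a single noise spike, which both
  inflates SUVmax and destabilizes every max-anchored method.
* **Ground truth.** The voxelized ellipsoid (voxel centre inside), fixed
  before blur and noise. It is deliberately independent of the image, so
  accuracy comparisons are against the simulated object, not against any
  segmentation-flavoured reference.

What the phantom does **not** model: projection-space reconstruction,
scatter and attenuation, respiratory motion, non-ellipsoidal lesion shapes,
and anatomical background structure. Conclusions from the suite are
statements about the pipeline's behaviour under a controlled, simplified
image formation model — they demonstrate correctness and internal
consistency of the machinery, not clinical performance.

## Initial masks

Two mask styles mimic how a reader crops a lesion:

* **Rectangular**: the ground-truth bounding box dilated by 3 voxels.
* **Irregular**: the ground truth dilated by 2 voxels, with a seeded random
  perturbation of the boundary (each outermost-ring voxel dropped, and each
  next-ring voxel added, with probability 0.3), minus the distractor region
  grown by 2 voxels. The generous exclusion reflects practice — a reader
  cropping out a hot structure removes its halo too, not just its core.

Both masks always contain the ground truth; only the irregular style
excludes the distractor, which is exactly the asymmetry the experiment
probes.

## Segmentation methods

All methods operate strictly inside the initial mask, work on the cropped
bounding box of the mask (identical results, much less work), and keep the
largest 26-connected component of their raw output.

* **41MAX** — voxels at or above 41% of the within-mask maximum.
* **ST** (contrast-oriented thresholding) — iterates
  `T = a * mean(high-uptake region) + b * background`, where the
  high-uptake region is the 70% isocontour of the current contour and the
  background is the mean intensity in a shell between the 2- and 4-voxel
  dilations of the current contour. The published calibration of `(a, b)`
  is scanner-specific and not reproducible here; the defaults
  `a = b = 0.5` are exposed in `st_params()` and behave like a
  mid-contrast threshold. Iteration stops when the contour is unchanged,
  the threshold moves less than `tol = 1e-4` SUV, or after 30 iterations
  (flagged as non-converged).
* **AP** (affinity propagation) — exemplar-based clustering of voxel
  intensities (similarity = negative squared difference, preference =
  median similarity, damping 0.9, deterministic message passing). Masks
  larger than 800 voxels are subsampled with a seeded draw and labels
  propagate to the remaining voxels by nearest intensity. The clusters are
  binarized by keeping every cluster whose exemplar exceeds half the
  within-mask maximum (`hot_fraction = 0.5`); `ap_params()` also offers
  `foreground = "max_uptake"` (only the cluster holding the hottest voxel)
  and `foreground = "largest"` (the literal biggest grouping). The default
  was chosen because the biggest grouping inside any bounding-box mask is
  arithmetically guaranteed to be background — an ellipsoid can fill at
  most ~52% of its own bounding box — which produces segmentations many
  times larger than the lesion; the hot-class rule keeps AP
  at lesion scale while leaving it visibly the least stable method, which
  is the behaviour the consensus contour is meant to absorb. If message
  passing does not converge within 500 iterations the method falls back to
  a two-class Otsu split of the intensities (hot class kept) and flags the
  result.
* **MASAC** (region-based active contour) — a two-region
  piecewise-constant energy (Chan–Vese type) restricted to the initial
  mask, with a boundary-length penalty weighted by `lam = 3` (boundary
  measured as physical face area, cm²). The contour is initialized from
  the 41MAX result and evolved by deterministic iterated conditional modes
  sweeps in voxel scan order; region means are refreshed once per sweep.
  Evolution that empties or fills the mask returns the initialization,
  flagged. This is a surrogate for the published algorithm of the same
  role, which is not fully specified in the source we implement from; the
  smoothness weight honours the published setting.

## Consensus contour

`majority_vote()` includes a voxel when at least `vote_threshold` of the
input masks include it; `conseg()` fuses the four methods at the default
strict majority (3 of 4) and keeps the largest component. The threshold is
a config knob because consensus work in this area has used both strict
majority and ≥50% rules; if the consensus is empty the threshold is lowered
by one and the result flagged. The fused mask always lies between the
intersection and the union of its inputs and is invariant to input order.

## Feature extraction

`extract_all()` computes the full 107-feature catalog — 14 shape, 18 first
order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM — following the
public IBSI-aligned catalog's definitions, on SUV images discretized with a
fixed bin width of 0.25 SUV anchored at the ROI minimum
(`label = floor((x - min) / 0.25) + 1`). No resampling and no image
filters are applied. Conventions worth knowing:

* Texture matrices are built in 3-D over the 13 unique direction offsets
  of the 26-neighbourhood at distance 1; GLCM matrices are symmetrized and
  features averaged over directions with equal weights, GLRLM features are
  averaged the same way, GLSZM/GLDM/NGTDM are direction-free. Voxels
  outside the ROI never contribute to any count.
* Gray levels enter formulas as bin labels; normalizing constants use the
  number of levels present in the ROI. GLDM dependence is 1 plus the
  number of in-ROI neighbours within `alpha = 0` levels; NGTDM excludes
  voxels with no in-ROI neighbour and returns the conventional 10^6 for
  Coarseness when the weighted difference sum is zero.
* First-order moments use raw SUV values; Entropy and Uniformity use the
  discretized probabilities; percentiles interpolate linearly between
  order statistics; skewness and kurtosis of a constant ROI are defined as
  0, and kurtosis is not excess kurtosis. Log terms add a machine-epsilon
  guard.
* Shape features are mesh-based: the 0.5-isosurface of the binary mask is
  triangulated by marching tetrahedra on a 24-tetrahedra-per-cell
  subdivision (cube centre and face centres carry averaged indicator
  values), giving a watertight mesh whose enclosed volume follows from the
  divergence theorem. Flat axis-aligned boundaries reconstruct the exact
  mid-plane between in and out voxel centres. Like every mesh extracted
  from binary data (including the reference implementations in this
  field), the surface bevels edges and corners, so `MeshVolume` of a
  blocky mask is a few percent below voxel count × voxel volume, and the
  sphericity of a voxelized ball plateaus around 0.9 rather than reaching
  1. Axis lengths come from the eigenvalues of the voxel-centre
  covariance; maximum 2-D/3-D diameters use boundary voxel centres.
* Features that are undefined on an input — correlation-type GLCM features
  on a single gray level, elongation of a single voxel, NGTDM on a
  neighbourless ROI — are returned as `NA` and marked in the `invalid`
  attribute; they are never silently zero.

## Reliability analysis

`icc_a1()` implements the single-measure, absolute-agreement intraclass
correlation under a two-way random-effects model,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

from the two-way ANOVA mean squares (rows = subjects/cases, columns =
raters). Three designs map the feature table onto measurement matrices:
`between_masks` (per method, k = 2 mask styles), `among_methods` (per mask
style, k = 4 individual methods), and `vs_ground_truth` (per
method × mask, k = 2, synthetic suites only). Features invalid in any cell
of a group are excluded for that group and counted. Negative ICC estimates
— expected occasionally at n = 13 — are kept in the per-feature output
with a flag and excluded only from the category-count summaries, with the
excluded fraction reported, so nothing disappears silently.

Categories follow the fixed partition on the absolute value: excellent
(≥ 0.9), good (0.75–0.89), moderate (0.5–0.74), poor (< 0.5). The good
category is implemented as [0.75, 0.9) so the printed bands partition
without gaps. Summaries report per-group category counts, median ICC, and
the stable-feature set: features at or above 0.75 in **every** group of
the supplied table (with the ≥ 0.9 subset alongside), as a count and as a
percentage of the 107-feature catalog.

## Feature correlation structure

`spearman_matrix()` computes pairwise Spearman correlations across cases
(average ranks under ties; constant columns are flagged and yield `NA`).
`reference_order()` gives an average-linkage hierarchical-clustering leaf
order on the distance 1 − |ρ| (undefined entries treated as distance 1),
so one matrix's ordering can re-render another for visual comparison.
`compare_matrices()` condenses "do two settings share correlation
structure" into the Pearson correlation of the vectorized upper triangles;
it has no printed counterpart in the literature this package follows — it
exists to make a visual claim testable.

## Determinism and numerical choices

Every random draw derives from one master seed: `run_experiment()` expands
it into per-stage, per-case streams with a seeded `sample.int`, and each
consumer (texture field, noise, mask jitter, AP subsample) restores the
RNG state afterwards. Two runs with the same configuration are
bit-identical in masks and features. Ties break deterministically
everywhere: connected components label in scan order, AP resolves argmax
ties to the lowest index, ICM sweeps in linear voxel order.

Problem sizes used by the test suite are the package defaults: the
13-case suite at full grid size for the end-to-end checks, with five
replicate suites for the stability-across-seeds property, and small
analytic toys for the per-operation oracles.

## Known limitations

* With 13 cases and two mask styles, mask-style contrasts (e.g. counts of
  excellent features per style in the among-methods design) are noisy;
  individual suites can invert the typical ordering. The end-to-end checks
  therefore pin the suite seed, and the stability claims that matter
  (consensus at least as robust as the weakest method; Energy/Maximum in
  the stable set) are asserted across replicate suites.
* The mesh volume is not the voxel-count volume (see above); both are
  reported as separate features.
* The AP binarization rule is a documented design choice among three
  implemented variants; the literal largest-grouping reading is available
  but degenerates in loose masks.
* Accuracy comparisons use the noise-free voxelized ellipsoid as truth;
  partial-volume effects mean even a perfect method cannot reach ICC 1 on
  intensity features.
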