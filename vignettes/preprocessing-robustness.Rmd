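---
title: "How image preprocessing moves radiomic features on cardiac T1/T2 maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How image preprocessing moves radiomic features on cardiac T1/T2 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cmradiomics)
library(dplyr)
```

## The problem

Quantitative cardiac MR maps assign each pixel a physical tissue property —
the longitudinal (T1) or transverse (T2) relaxation time in milliseconds —
so radiomic descriptors computed from them are candidates for detecting
diffuse myocardial disease that eludes visual reading. But every radiomic
value is conditional on preprocessing: the grid the map was resampled to,
the width of the bins used to quantize intensities into gray levels, and any
spatial filter applied beforehand. If a feature moves more under a plausible
change of preprocessing than it does between patients, it cannot carry
clinical signal across sites.

This package quantifies that sensitivity for single-slice myocardial T1/T2
maps with an annular ("ring") region of interest, through three designs:

* **Effect A** — vary the resampling voxel size (1.8–2.4 mm in 0.1 mm
  steps) at each fixed bin width;
* **Effect B** — vary the bin width (3.60–6.40 ms in 0.35 ms steps for T1;
  0.49–0.57 ms in 0.01 ms steps for T2) at each fixed voxel size;
* **Effect C** — at fixed voxel size (2.1 mm) and bin width (6 ms T1 /
  0.56 ms T2), vary the spatial filter over seven candidates: the four
  sub-bands of a single-level undecimated Daubechies-3 wavelet transform,
  the gradient magnitude, the per-pixel square, and the per-pixel square
  root of the absolute value.

Effects A and B are two slicings of the same 7 × 9 voxel-by-bin feature
grid, which the pipeline extracts once per subject and reuses.

## Variability statistics

For each feature and effect, subjects form rows and preprocessing
conditions form "raters" of a two-way crossed layout. Relative variability
is the intraclass correlation for a two-way mixed model, single rater,
absolute agreement:

$$\mathrm{ICC} = \frac{MS_R - MS_E}
{MS_R + (k-1)\,MS_E + \tfrac{k}{n}\,(MS_C - MS_E)}$$

with $MS_R$, $MS_C$, $MS_E$ the between-subject, between-condition and
error mean squares, $n$ subjects and $k$ conditions. Values are stratified
into half-open bands: high (ICC ≤ 0.5), considerable (0.5–0.75), moderate
(0.75–0.9) and low (0.9–1) variability; boundary values fall in the lower
band. A matrix whose cells are all identical makes the ratio 0/0; it is
resolved to ICC = 1 with a degeneracy flag, because a feature that never
moves is the limiting case of minimal variability.

Absolute variability is the per-subject coefficient of variation,
$100 \cdot \mathrm{SD}/|\bar x|$ over the varied conditions (sample SD,
denominator $n-1$; undefined when the mean is zero). Linear trend is the
repeated-measures correlation: an ANCOVA of feature on preprocessing value
with subject as a factor and a common slope, reported as
$r_{rm} = \mathrm{sign}(b)\sqrt{SS_x/(SS_x+SS_e)}$ with
$N(k-1)-1$ degrees of freedom for balanced designs, and Bonferroni
correction over the features tested within one modality × effect family.
The correction family follows that convention because no finer-grained
family definition is available; the alternative (counting conditions as
well) would only make flags more conservative.

Because the repeated-measures correlation needs one observation per
subject × condition, and the A/B grids have a second, fixed dimension, the
package runs it at a single fixed value of the complementary parameter
(default: the median of its grid). Running it at every fixed value and
correcting across the larger family is possible by calling
`analyze_effect()` per slice.

## The feature engine

The inventory is the closed 98-feature 2D set: 9 shape features, 16
first-order features, and 73 texture features from GLCM (22), GLRLM (16),
GLSZM (16), GLDM (14, dependence threshold α = 0) and NGTDM (5), all with
Chebyshev distance 1. GLCM and GLRLM are directional: features are computed
per angle (0°, 45°, 90°, 135°) and then averaged over angles — averaging
feature values, not matrices. Filtered maps drop the shape class (shape
depends only on the mask), leaving 89 features.

Choices that matter for reproducing numbers bit-for-bit:

* **Discretization** uses a fixed bin width with bin edges anchored at
  integer multiples of the width:
  `level(x) = floor(x/W) - floor(min/W) + 1`. Anchoring at the ROI minimum
  is available as an option. The study bin-width grids were chosen so a
  typical ROI range (median 265 ms for T1, 26 ms for T2) lands on 30–130
  gray levels; `count_levels()` reproduces that criterion, reporting the
  phase-maximal or phase-minimal count since the exact count depends on
  where the ROI minimum falls between bin edges.
* **First-order statistics** (mean, variance, skewness, Pearson kurtosis,
  percentiles with linear interpolation, MAD and robust MAD, energy, RMS)
  are computed on the continuous intensities *before* discretization; only
  Entropy and Uniformity use the discretized histogram. This is why shape
  and the 14 intensity statistics are structurally invariant under effect
  B: the bin width never enters their computation, forcing ICC = 1 and
  CV = 0 % exactly. The package treats that forced result as a correctness
  check of the pipeline plumbing. Kurtosis is reported in non-excess
  (Pearson) form, i.e. excess kurtosis + 3.
* **Undefined values** (zero variance for GLCM correlation, log of an
  empty distribution, zero NGTDM denominators) become `NA`, never a silent
  0, and propagate to listwise deletion of subjects in the ICC matrices
  with dropped counts logged. The single deliberate exception is NGTDM
  Contrast, defined as 0 when only one gray level is present, which is the
  value the defining formula approaches as tone differences vanish.
* **Sparse matrices.** Gray-level matrices are stored as sparse triplet
  tables and every texture formula is evaluated as a weighted sum over
  nonzero entries (with the identity HXY2 = HX + HY for Imc2). This is not
  an optimisation nicety: the literal square filter maps T1 intensities
  near 1000 ms to ~10⁶ ms², and a fixed 6 ms bin then yields on the order
  of 10⁵ gray levels, where a dense N² co-occurrence array is not
  representable. Dense forms are materialised alongside whenever small.
* **Shape** uses marching squares on the binary mask at iso-level 0.5
  (crossings at edge midpoints; saddle configurations keep diagonal
  corners separate) for mesh surface, perimeter and maximum diameter, and
  the eigendecomposition of the physical pixel-coordinate covariance
  (denominator n − 1) for the axis features. The staircase contour of a
  digital disk keeps the mesh perimeter a few percent above the ideal
  circle, so sphericity saturates slightly below 1.

## Preprocessing operators

**Resampling** interpolates the map with a cubic B-spline (exact recursive
prefilter, mirror boundary) on an output grid that shares the input origin
and covers the input extent without extrapolation; the mask is resampled by
nearest neighbour and re-binarized at 0.5 so no fractional membership
arises. Identity resampling reproduces the input to floating-point
accuracy, and constants are preserved exactly. The mask convention and the
mirror boundary are conventional defaults; the interpolant itself is
validated against an independent B-spline evaluation in the tests.

**Filters.** `square` and `square-root` are the literal per-pixel algebra
(x², √|x|), deliberately *not* the range-rescaled variants some toolkits
substitute; with the fixed effect-C bin widths this has visible
consequences — the square filter explodes the level count (handled by the
sparse engine) and the square-root filter compresses a T1 map's range below
one bin width, collapsing the discretization to a single level and flagging
level-dependent features undefined. Both behaviours are the honest reading
of per-pixel algebra plus fixed-width binning and are surfaced rather than
hidden. The wavelet transform is single-level, undecimated (à trous) with
periodic boundary extension so each sub-band stays congruent with the grid;
analysis filters carry a 1/√2 per-axis normalisation so the LL band of a
constant map keeps the original intensity scale, and the adjoint synthesis
reconstructs the input exactly (tested to 10⁻⁶). The gradient filter is the
spacing-aware central-difference magnitude (one-sided at edges), in ms/mm.

## The synthetic cohort

The study population this package emulates is not distributable, so a
seeded generator stands in for it. Each subject gets:

* a native isotropic spacing drawn uniformly from [1.77, 2.34] mm,
  mimicking acquisition heterogeneity and making resampling non-trivial;
* an annular myocardial ROI (default radii 20–30 mm on a 126 × 192 grid),
  a few hundred pixels at these spacings;
* within-ROI texture: white Gaussian noise convolved with a Gaussian
  kernel of width `correlation_length_mm` (default 6 mm), normalised to
  unit pointwise variance and scaled by a fixed constant
  `target_median_range_ms / 4.09`, where 4.09 is the expected within-ROI
  range of the unit field at the default geometry, fitted once across
  seeds. The scaling is deliberately a constant rather than an adaptive
  renormalisation: as the correlation length grows the field genuinely
  flattens and the range goes to zero, which an adaptive rescale would
  mask. With defaults, the median across-subject range calibrates to
  265 ms (T1) or 26 ms (T2) within a few percent;
* a per-subject additive mean shift (SD 60 ms T1 / 3 ms T2 around means of
  1030 / 50 ms — configuration values typical for myocardium, not claims),
  which guarantees $MS_R > 0$ so the ICC is well defined;
* a background at the low tail of the myocardial distribution
  (mean − range/2, small noise). The background never enters feature
  estimation directly, but B-spline resampling blends it into rim pixels,
  so it is kept close enough that the post-resampling ROI range — and with
  it the gray-level count — stays inside the intended 30–130 band.

What the generator does **not** emulate: acquisition physics (MOLLI
fitting, T2 preparation), motion, partial-volume anatomy (blood pool,
fat), segmentation variability, or 3D geometry. Passing tests on this
cohort therefore demonstrate correctness of the estimator pipeline and of
the structurally forced results, not clinical-level effect sizes; the
ICC/CV magnitudes for texture features on real patients depend on real
myocardial texture and are expected to differ.

## Numerical and design notes

* Determinism: all randomness flows from the spec seed; the generator
  saves and restores the caller's RNG state.
* The level count under multiples-of-W anchoring is non-increasing in W up
  to a ±1 phase fluctuation (exact monotonicity holds for roi-minimum
  anchoring); the phase-extremal counts are what `count_levels()` reports.
* Effect C excludes the unfiltered map from the rater set by default (the
  seven filters are the conditions); `include_original = TRUE` restores it
  for comparison.
* Listwise deletion is per feature × fixed condition; an ICC needing at
  least 2 subjects and 2 conditions after deletion is otherwise reported
  as `NA`.
* Problem sizes used in the shipped tests (small grids, 2–26 subjects,
  restricted grids) were chosen to exercise every code path at
  interactive speeds; all constants above are independent of those sizes.

## A worked run

```{r, eval = FALSE}
co <- generate_cohort(cohort_spec(n_subjects = 26, modality = "T1",
                                  seed = 42))
design <- default_designs("T1")$B
design$voxel_sizes_mm <- 2.1          # one fixed voxel size
feats <- run_effect(co, design)
ana <- analyze_effect(feats, design)

ana$icc |>
  filter(feature_class == "shape") |>
  count(band)
#> all 9 shape features: band "low", ICC = 1 exactly

autoplot(ana)                          # ICC band heatmap
plot_cv_distribution(ana, "glcm")      # per-subject CV boxplots
```
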