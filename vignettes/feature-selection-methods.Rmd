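---
title: "Dual-pathway feature selection for fire-ant mound discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-pathway feature selection for fire-ant mound discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Red imported fire-ant (*Solenopsis invicta*, RIFA) mounds are compact
soil structures, typically a few decimeters across, that disturb
vegetation and expose bare soil.  In five-band UAV surface-reflectance
imagery (blue, green, red, red-edge, NIR) they can be told apart from
bare soil, water-containing soil, asphalt, cement, and grass — but only
through the right features.  `rifasel` implements the feature-engineering
and feature-selection stage of that workflow: it expands a scene into 38
candidate features per analysis unit, scores them at two spatial scales,
prunes redundancy along two complementary statistical routes, and
summarizes which features are stably informative.  It deliberately stops
short of fitting any classifier: the deliverable is a ranked,
de-redundified feature set, not a detector.

## The feature stack

Each analysis unit carries 38 features:

* **5 spectral bands** — surface reflectance in blue, green, red,
  red-edge, NIR (unitless, nominally in [0, 1]; values outside
  [−0.05, 1.5] are tolerated as radiometric artifacts and only counted).
* **3 vegetation indices** —
  NDVI = (NIR − R)/(NIR + R), SAVI = (NIR − R)(1 + L)/(NIR + R + L) with
  soil brightness factor L = 0.5, and PPR = (G − B)/(G + B).  L is fixed
  at 0.5 by default but exposed as a parameter.  Pixels with a zero
  denominator are masked rather than propagated as NaN, and masked
  pixels drop out of all downstream tables.
* **30 texture measures** — for each band, six gray-level co-occurrence
  matrix (GLCM) statistics of the window centered on each pixel:
  homogeneity Σ g/(1+(i−j)²), contrast Σ (i−j)² g, dissimilarity
  Σ |i−j| g, entropy −Σ g ln g (natural log, 0·ln 0 := 0), angular
  second moment Σ g², and correlation Σ (i−μ)(j−μ) g / σ².

GLCM defaults are a 3×3 window, 64 gray levels, the four standard
displacement directions (1,0), (0,1), (1,1), (1,−1) averaged after
per-offset normalization, symmetric pair counting, and per-band min–max
quantization over valid pixels.  The software that originally
popularized these texture measures does not document a single canonical
windowing, so numerical identity with any specific GIS product is not
claimed; all settings are explicit in `glcm_spec()` and the pipeline
config.  Two conventions are worth calling out:

* **Degenerate correlation.** A constant window has zero GLCM marginal
  variance; its correlation is defined as 1 (the limit of a perfectly
  dependent degenerate distribution).  This keeps flat surfaces such as
  cement and asphalt from producing NaNs.
* **Border handling.** A pixel whose window leaves the scene or touches
  a nodata pixel is masked, and any unit containing a masked value in
  any feature is excluded (with a count) rather than imputed.

## Two scales, two routes

Units are either **pixels** (every ROI pixel is a row) or **objects**
(one row per ROI, each feature the arithmetic mean of the ROI's usable
pixels).  The object mean is taken over exactly the pixel set that
survives masking, so an object row equals the mean of its pixel rows —
an identity the test suite checks exactly.  Means are taken of the
per-pixel feature planes (including texture), not features of an
averaged image.

Each scale's table is then pruned along two routes:

* **Linear route.** One-way ANOVA F-scores (between- over within-class
  variance; a pure ranking statistic, no p-values) order the features;
  a greedy pass then drops any candidate with Pearson |r| > 0.7 against
  an already-retained feature.  A feature with zero within-class but
  positive between-class variance receives an `Inf` sentinel and ranks
  first.
* **Nonlinear route.** Recursive feature elimination under a random
  forest (impurity importance, removing the least important feature per
  round; each feature's score is its importance just before removal,
  the ranking is the reverse elimination order, and nothing is discarded
  at this stage) orders the features; the greedy pass then uses the
  maximal information coefficient (MIC) with the same 0.7 threshold,
  which flags monotone and other nonlinear redundancies that Pearson
  correlation can miss.

The greedy keep-best convention — visit features in descending score,
drop on the first conflict with the retained set, break ties by the
fixed column order — is our resolution of an ambiguity: the pairwise
"drop the lower-scored member" rule does not by itself say what happens
in transitive correlation clusters (A~B, B~C, A≁C).  Greedy keep-best is
deterministic, keeps each cluster's best representative, and guarantees
the post-condition that no retained pair exceeds the threshold; the drop
log records every elimination with its kept partner, association value
and rule so alternative conventions can be compared.

Associations are always computed on the same table being filtered (per
scale), never pooled across scales.  Constant features have undefined
association; they are treated as uncorrelated and kept only with a
positive score.

## MIC implementation

No MIC implementation is available among our dependencies, so the
package carries its own, following the MINE approximation: for every
grid shape p×q with p·q ≤ B(n) = n^0.6, one axis is mass-equipartitioned
into q bins (ties kept together), the other axis's cut points are
optimized by dynamic programming over clump boundaries, with the clump
count capped at c·p (c = 15); both orientations are searched, and MIC is
the maximum of I/ln(min(p, q)).  The DP is exact over the searched grid
family; the test suite verifies it against an independent exhaustive
enumeration of all cut positions for n ≤ 30, where the superclump cap is
never active and exact agreement is the correct expectation (for larger
n the cap may bite, which is the approximation's documented behavior).
MIC is 1 for any noiseless functional relationship, 0 for a constant
input by convention, and symmetric by construction.

The forest spec defaults to 500 trees, one feature removed per RFE
round, impurity importance, and an explicit seed; every stochastic
operation takes a seed and the whole pipeline is bit-reproducible given
a config.

## Integration

The four configurations (linear/nonlinear × pixel/object) are merged
into a comparison report: per-method min–max-normalized scores (the
heatmap matrix; `Inf` sentinels map to the method's maximum before
scaling, and an all-equal score vector normalizes to all 1), per-method
retention flags, each feature's retention frequency (count/4 — a
stability proxy), the unweighted mean of the four normalized scores, and
the per-method top-10 among retained features.  "Standardized within its
method" is interpreted as min–max to [0, 1] because the summary figure
this mirrors is a normalized-importance heatmap; z-scoring is available
as a config alternative.  Weights for the cross-method average are not
specified anywhere authoritative, so they default to equal and are
exposed in the config.  The two routes can also be merged per scale as a
plain union of retained sets with duplicates removed.

## The synthetic generator

The study's field imagery is not public, so the generator is the
package's stand-in input and the substrate of its validation suite.  A
scene is a background of five vertical class strips (bare soil, water
soil, asphalt, cement, grass) with circular mounds planted on top
without overlap.  Per-pixel band values are

```
median[class, band] * (1 + tex_frac[class] * T) + sd_iid * Z
```

where `T` is a toroidal box-blurred unit-variance Gaussian field with a
class-specific correlation length (short for mounds and grass — rough
texture; long and weak for asphalt and cement — smooth), `Z` is i.i.d.
standard normal, and `sd_iid` combines a brightness-proportional term
with an absolute noise floor in quadrature.  All noise is symmetric with
zero median, so per-class band medians are preserved by construction.

Defaults encode the study conditions:

* Class band medians use the reported pixel-level values where printed
  (mound blue/green/red/NIR 0.012/0.023/0.018/0.0428; asphalt
  0.030/0.065/0.061/0.0569; cement NIR 0.048; grass NIR 0.089).  Bare
  soil, cement, and grass reds are back-solved so the class NDVI medians
  land at their reported values (−0.123, −0.016, 0.636); grass NDVI
  0.636 is the generator's calibration target and is verified to ±0.03
  in the acceptance suite.  Red-edge medians are not reported per class
  and are synthetic: interpolated midway between red and NIR.
* One reported figure cannot be matched simultaneously: the mound band
  medians imply a mound NDVI around 0.4 at the medians, while the
  reported mound pixel NDVI median is 0.085.  Both can coexist in real
  imagery only through skewed, mixed-pixel distributions that this
  symmetric-noise generator intentionally does not model; we match the
  band medians and the grass NDVI target.
* Spreads are not reported.  The baseline is an interquartile range of
  30% of the class median, modulated per band (visible ×1.4, red-edge
  ×0.85, NIR ×0.7) plus an absolute noise floor of 0.01 reflectance —
  a typical radiometric accuracy for UAV surface-reflectance products.
  This mirrors the reported structure of the imagery (mounds show low
  reflectance with high variability in the RGB bands, while the NIR
  signal is comparatively stable) and is what makes the generator's
  design target hold: purely proportional noise would make the
  near-zero-median visible bands unrealistically clean and let them
  dominate every ranking.
* The default layout plants 10 mounds (radius 2–3 px) and six 3×3
  ROI patches per background class on a 70×70 grid — enough replication
  at both scales to keep the object-level statistics stable while a
  pixel table of ~450 units stays tractable for the all-pairs MIC
  filter on a single CPU.

What the generator does **not** emulate: mixed border pixels,
georeferencing error, illumination gradients, shadows, skewed
reflectance distributions, and spatial autocorrelation between bands.
Passing recovery tests therefore demonstrate that the selection
machinery finds planted structure under controlled conditions — not
that the same features would win on any particular field dataset.

The tabular generator plants known structure for recovery tests:
informative features with class-separated means (adjacent classes 1.5
within-class standard deviations apart by default), redundant features
that are either noisy linear copies (redundancy = target correlation,
0.95) or near-functional monotone transforms (an exponential warp;
redundancy sets one minus the relative noise, because MIC needs a much
tighter relationship than |r| to exceed the same 0.7 threshold at
n ≈ 100), and pure-noise features.  The default scenario is 3 classes ×
40 rows, 3 informative + 2 redundant + 5 noise features.

## Problem sizes and numerical choices

The validation suite runs everything at desk scale, chosen as the
package's own trade-off between statistical resolution and runtime on a
single CPU: generator-fidelity checks use ≥10⁴ pixels per class
(360×360 scenes with 120 planted mounds), redundancy post-conditions
use 50 seeded tables, planted-feature recovery uses 100 seeds at the
default table scenario with the default 500-tree forests, and the
end-to-end qualitative check runs the full pipeline on 50 seeded
default scenes with 150-tree forests (the RFE ranking is already stable
at that size for 38 features and ~450 units; the package default stays
at 500).  Tie-breaks everywhere follow the fixed canonical feature
order (bands, indices, then textures band-major), which makes permuting
input columns a no-op apart from genuine ties.

## Known limitations

* Scene I/O is plain multi-directory TIFF plus a JSON sidecar for band
  scaling, mask, affine transform and CRS; GeoTIFF geo-tags themselves
  are neither read nor written, and reprojection is out of scope (ROI
  coordinates must share the scene's frame).
* Reflectance is passed through unclipped; the package tolerates
  modestly out-of-range values rather than "fixing" them.
* Object definition is the provided ROI; automatic segmentation is out
  of scope, as is any trained classifier.
* The RFE ranking depends on forest hyperparameters and the seed; only
  the procedure, not any exact published ranking, is reproduced.
* MIC for n in (30, 50] with many rows per grid can fall below the
  exhaustive grid optimum when the superclump cap engages — inherent to
  the approximation, not a defect.
* Stability is summarized only as retention frequency across the four
  configurations; no fold-based coefficient of variation of scores is
  computed, since there is no authoritative definition of one for this
  workflow.
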