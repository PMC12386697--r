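# rifasel

Feature extraction and dual-pathway feature selection for UAV
multispectral detection of red imported fire-ant (*Solenopsis invicta*)
mounds.

Fire-ant mounds are small soil structures that disturb vegetation and
expose bare ground.  In five-band UAV surface-reflectance imagery (blue,
green, red, red-edge, NIR) they can be discriminated from bare soil,
water-containing soil, asphalt, cement, and grass — if the right
features are used.  `rifasel` is for remote-sensing ecologists and
invasive-species monitoring teams who need to know *which* features
carry that signal before building any detector.  The package builds the
candidate feature set, scores it at two spatial scales, removes
redundancy along two statistical routes, and reports which features are
stably informative.  It fits no classifier.

## What it computes

Every analysis unit (a pixel, or an ROI treated as one object with
mean feature values) carries **38 features**: the five bands; the
vegetation indices

* NDVI = (NIR − R) / (NIR + R)
* SAVI = (NIR − R)(1 + L) / (NIR + R + L),  L = 0.5
* PPR  = (G − B) / (G + B)

and six gray-level co-occurrence (GLCM) texture measures per band
(homogeneity Σ g/(1+(i−j)²), contrast Σ (i−j)²g, dissimilarity Σ |i−j|g,
entropy −Σ g ln g, second moment Σ g², correlation
Σ (i−μ)(j−μ)g/σ²) over a sliding window.

Features are then ranked and pruned along two routes, per scale:

* **linear** — one-way ANOVA F-scores, then greedy removal of features
  with Pearson |r| > 0.7 against a better-scored retained feature;
* **nonlinear** — random-forest recursive feature elimination (RFE)
  for a global importance ranking, then greedy removal of features with
  maximal information coefficient (MIC) > 0.7 (an in-package MINE
  implementation; MIC also catches monotone and other nonlinear
  redundancy).

The four method × scale configurations are integrated into a
normalized-importance matrix (heatmap-ready), per-feature retention
frequencies, averaged importances, and per-method top-10 lists.  A
seeded synthetic-scene generator, calibrated to the per-class
reflectance medians reported for the original study site, provides
fully labeled inputs and ground truth for validation.

## Worked example

```r
library(rifasel)

# a labeled synthetic scene: 70x70 px, 10 planted mounds,
# 5 background classes, seeded for exact reproducibility
cfg <- pipeline_config(rfe = list(n_trees = 150), seed = 42)
res <- run_pipeline(cfg)

res$tables$pixel
#> <feature_table scale=pixel> 464 units x 38 features, 0 dropped
res$tables$object
#> <feature_table scale=object> 40 units x 38 features, 0 dropped

res$selections$linear_pixel
#> <selection_result route=linear> 25/38 features retained (threshold 0.70)

res$report
#> <comparison_report> 4 methods x 38 features
#> top averaged features: blue (0.99), red (0.49), SAVI (0.49), nir (0.46), rededge (0.45)

round(head(sort(res$report$retention_frequency, decreasing = TRUE), 4), 2)
#>             blue              nir              PPR blue_correlation
#>                1                1                1                1
```

Reading the output: the pixel table has one row per usable ROI pixel
(464 here), the object table one row per ROI (10 mounds + 6 background
patches for each of the 5 non-mound classes).  Each selection result
carries the scores, the ranking, the retained set, and a drop log
naming, for every eliminated feature, the retained partner and the
association value that triggered the rule.  The report's averaged
importances show the pattern the workflow is designed to surface: the
spectral bands, the NIR band and a vegetation index (SAVI here) lead,
while texture features rank low and are retained rarely.  (Numbers
above are from this exact seed; other seeds give the same qualitative
picture.)

File-based scenes work the same way: point
`pipeline_config(scene = list(raster = "scene.tif", rois = "rois.geojson"))`
at a five-band TIFF and a GeoJSON FeatureCollection whose features carry
an integer `class_id` property (1 = mound, 2 = bare soil, 3 = water
soil, 4 = asphalt, 5 = cement, 6 = grass).  A command-line wrapper with
the same stages lives in `inst/cli/rifasel.R`.

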