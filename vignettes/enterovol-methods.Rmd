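---
title: "Measuring ileal inflammation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ileal inflammation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the
measurement models, the parameters that matter, the numerical decisions,
and what the synthetic phantoms can and cannot tell you about real
enterography.

## The measurement problem

Active ileal Crohn disease appears on T2-weighted single-shot fast
spin-echo (SSFSE) enterography as a thickened, intermediate-intensity
bowel wall around a bright fluid-distended lumen. Clinical reading
reduces this to two linear numbers — maximum wall thickness (mm) and
length of disease (cm) — both operator-dependent. A volumetric
assessment segments the wall from outer serosa to inner mucosa along the
whole diseased segment and reports its volume in mL; because it
integrates thickness over length, its *relative* change under effective
therapy is mechanically at least as large as either linear measure's
(if thickness shrinks by factor $f_t$ and length by $f_l$, wall volume
shrinks approximately by $f_t f_l$). The package implements all of these
measurements plus the statistics used to compare their responsiveness.

All modules share one geometric convention: axis-aligned grids, physical
millimetre coordinates, origin at the grid corner, 0-based voxel index
$i$ centred at $(i + 0.5)\,s$ for spacing $s$. The default grid mimics
the acquisition geometry: 1.3 mm in-plane, 5 mm slices.

## Centerline and length of disease

The operator clicks ordered seed points along the lumen;
`interpolate_centerline()` fits a natural cubic interpolating spline per
coordinate on a chord-length parameterization and resamples it by arc
length. Interpolation (not smoothing) is deliberate: the curve passes
through every seed, so length responds only to where the operator
clicked, never to a smoothing penalty. The resampling step
(`step_mm = 0.5`) is well below in-plane voxel spacing; halving it
changes length by under 0.1%, so resampling error is negligible against
seed placement. Exact duplicate consecutive seeds are collapsed with a
warning; a fully coincident seed set is rejected. Length is maintained
at full precision internally and reported at 0.1 cm.

## Semi-automated wall segmentation

Given the centerline, the segmenter works in four stages:

1. **ROI**: voxels within `roi_radius_mm` (default 15 mm) of the
   centerline — generous enough for a thickened wall plus margin.
2. **Partitioning**: k-means (`k = 40` per ROI) on standardized
   intensity plus physical coordinates scaled by
   `spatial_weight / (ROI volume / k)^(1/3)` (`spatial_weight = 0.5`), a
   SLIC-like compactness trade-off; every cluster is then split into
   face-connected (6-connectivity) components so each partition is
   contiguous. `k = 40` makes partitions smaller than wall structures
   but large enough for stable statistics; both knobs are exposed.
3. **Scoring**: each partition is described by nine features — voxel
   count, physical volume, mean/sd intensity, min/mean distance to the
   centerline, elongation (square root of the extreme principal-axis
   eigenvalue ratio), mean boundary gradient magnitude, and the fraction
   of voxels inside the expected wall annulus
   (`lumen_radius < d <= lumen_radius + wall_band_mm`). A random-forest
   regressor maps features to inclusion probability. Training targets
   are *soft*: the fraction of each partition inside the reference wall
   mask, matching a regressor-of-probability rather than a hard
   classifier. The feature set is this package's definition (intensity,
   geometry, and centerline-relative position are the three signals the
   approach requires) and is schema-checked at predict time.
4. **Assembly**: union of partitions with probability at or above
   `threshold = 0.5` (ties included), minus a *hard* geometric lumen
   exclusion (all voxels within the lumen radius of the centerline are
   removed regardless of the model's score — the wall-only convention is
   enforced even when the model errs), keeping only connected components
   that touch the expected wall band.

The lumen radius, when not supplied, is estimated from the radial
intensity profile around the centerline (0.5 mm bins). The boundary is
taken at the *steepest descent* of the profile within its bright part,
not at the halfway crossing: partial-volume averaging at 1.3 mm pixels
smears the profile outward, and the halfway crossing lands measurably
inside the wall (about +0.5 mm on phantoms), which in turn makes the
hard lumen exclusion carve true wall voxels. The inflection estimate is
nearly unbiased in the same experiment.

Manual masks enter through `validate_manual_mask()`, which enforces the
same convention: more than a small tolerated fraction of voxels inside
the lumen is an error, a handful are removed with a warning, and any
voxel implausibly far from the centerline rejects the mask outright.

## Morphometry

Volume is voxel count times physical voxel volume, reported at 0.1 mL.

Wall thickness uses 2D Euclidean distance transforms computed slice by
slice in the imaging plane, not a 3D transform: with 5 mm slices against
1.3 mm pixels a 3D distance would be dominated by slice thickness, and
wall cross-sections live in the acquisition plane. The slice axis is the
largest-spacing axis; in-plane spacing must be near-isotropic. Medial
("central") pixels are the 8-neighbourhood local maxima of the distance
map inside the wall; local thickness there is $2d - p$, where the $-p$
(one pixel) corrects the half-pixel offset between a background pixel
centre and the true boundary on each side. The mean over all medial
pixels is the segment-level mean wall thickness; the maximum is an
automated analog of the radiologist's caliper at the thickest point —
the two are kept as distinct columns and never conflated. A mask
nowhere thicker than one pixel cannot support the estimate; it reports
the pixel spacing and a low-confidence flag. Discrete medial maxima
sit slightly off the continuum ridge, so thickness is biased low by
roughly half a pixel to one pixel; all stated tolerances (half the
largest spacing for constant-thickness phantoms) absorb this.

## Longitudinal statistics

- **Change over time**: linear mixed-effects model per measurement,
  `value ~ timepoint + (1 | subject)`, REML, with the joint Satterthwaite
  F-test for the timepoint factor. Random intercept only: with 20
  subjects and 3 timepoints a random slope is not estimable reliably,
  and the intercept-only structure is the smallest consistent with
  repeated measures. Subjects with missed visits contribute their
  available rows (likelihood-based, no imputation). The model is fitted
  on the raw measurement scale, matching how such cohorts are analysed;
  its type-I error under the package's lognormal null generator is
  verified by simulation to sit at the nominal level.
- **Percent change** is computed from *group means*,
  $100(\bar{x}_{base} - \bar{x}_{follow})/\bar{x}_{base}$, rounded to
  integer percent. The alternative (mean of per-subject changes) is
  provided as an option (`per_subject_change = TRUE`); the group-mean
  form is the default because it is the definition consistent with every
  published group-mean/percent pair this package reproduces
  arithmetically.
- **Agreement** between manual and semi-automated volumes is ICC(2,1):
  two-way random effects, absolute agreement, single measures, computed
  from the two-way ANOVA mean squares, with the F-distribution
  confidence interval. Absolute agreement (not consistency) is the right
  form for "do the two methods give the same number"; qualitative bands
  at 0.50/0.75/0.90. The implementation is verified against an
  independent `aov()` mean-squares oracle to 1e-9 on fuzzed tables.
- **Correlations**: Pearson r with Fisher-z confidence intervals, all
  timepoints pooled, pairwise deletion.
- **Multiple testing**: none — five measurements are reported at
  p < 0.05 each, mirroring how such analyses are conventionally
  reported; interpret accordingly.

## The phantoms: what they emulate, and what they do not

`make_phantom()` rasterizes an annular tube along a smooth 3D curve:
voxel centres within the lumen radius get lumen intensity, within
lumen radius + wall thickness wall intensity, else background, plus
additive Gaussian noise (Rician magnitude noise is an option; Gaussian
is the default so the acceptance arithmetic stays closed-form). Two
numerical details matter:

- The curve is densely resampled at a quarter of the smallest spacing
  and distance-to-curve is evaluated at voxel centres (a small compiled
  kernel); voxels projecting beyond the endpoint tangent planes are
  clipped to background, so the rasterized tube has flat ends and
  matches the analytic annular-tube volume
  $\int \pi\,[(r+w(s))^2 - r^2]\,ds$ instead of a capsule's.
- The curve must clear the grid boundary by lumen + wall; otherwise the
  spec is rejected with a diagnostic.

Wall thickness may be a function of arc length (the built-in
cosine ramp exercises the max-vs-mean distinction). Default curves run
*through* the slice stack with in-plane undulation, so most slices cut
the tube close to transversely — the regime in which per-slice
thickness is meaningful. Intensity defaults (background 60, wall 130,
lumen 230) are plausible for SSFSE contrast but arbitrary; they are
config-exposed and no test depends on their specific values.

Phantoms do **not** simulate peristalsis, fat stranding, mesenteric
vessels, strictures with upstream dilation, skip lesions, bias fields,
or acquisition artefacts. Passing phantom tests therefore demonstrates
geometric and statistical correctness of the measurement chain — not
clinical performance on patient images, where wall/lumen contrast is
less clean and the vendor tooling differs in unknown ways (its
clustering space, feature set, threshold and post-processing are not
public, so no equivalence with it is claimed or tested).

Two cohort simulators sit on top. The measurement-level generator
(`make_longitudinal_cohort()`) draws, on the log scale, a shared
subject severity intercept (sd 0.55, matching the large between-child
spread of volumetric burden, CV ≈ 65%), per-timepoint multiplicative
shrink factors defaulting to the published group-mean ratios of a
20-child anti-TNF cohort, and visit-level noise (sd 0.25); the
semi-automated volume is the manual volume times the methods' mean ratio
times agreement noise (sd 0.20), so the two volume columns correlate
the way two segmentations of one bowel do. The study-style missingness
pattern (one subject baseline-only, two missing the 6-month visit) is
available as an option. The phantom-level generator
(`make_phantom_cohort()`) shrinks wall thickness and curve length
multiplicatively per timepoint and is measured by the package's own
pipeline, optionally through an operator-perturbation of the truth mask
(per-exam random boundary dilation/erosion, a few percent of volume).

## Problem sizes and seeds

The shipped tests and the acceptance script use 72 x 72 x 30-ish grids,
30 training + 10 held-out phantoms for the segmenter, 20 x 3 phantom
cohorts, and 500 replicates for the type-I simulation — sizes chosen so
the whole suite runs in minutes on a single core while keeping Monte
Carlo error well inside the asserted tolerances. One seeding subtlety:
consecutive integer seeds fed to R's Mersenne-Twister produce visibly
correlated cohort streams (null rejection rates drifted across
consecutive-seed blocks); all simulation loops therefore draw
per-replicate seeds from a single master stream via `sample.int()`.

## Known limitations

- Thickness is 2D per-slice; segments running parallel to the imaging
  plane inflate apparent thickness where a slice grazes the tube. The
  default phantom geometry avoids that regime; real bowel does not
  always.
- The NIfTI-1 header stores spacing as float32; spacing is snapped to 7
  significant digits on read so decimal mm spacings round-trip.
- The maximum-thickness column from the automated profile is an analog
  of, not a substitute for, a radiologist's manual caliper.
- ICC confidence intervals use the F-distribution approximation; with
  n = 20 pairs they are wide, exactly as in studies of this size.
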