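# enterovol

Linear and volumetric quantification of bowel inflammation on MR
enterography-like images.

In ileal Crohn disease, treatment response on MR enterography is
conventionally tracked with two linear measurements: maximum bowel-wall
thickness and length of disease. Both are operator-dependent — thickness
depends on *where* along the inflamed segment the caliper is placed, and
the bowel courses in and out of the imaging plane. A volumetric
assessment of the inflamed wall integrates thickness along the whole
diseased segment and is a candidate for a more responsive biomarker.
`enterovol` implements that measurement workflow end to end, for
radiology researchers who want to study it quantitatively with known
ground truth:

- **Centerline / length of disease** — a natural cubic interpolating
  spline through operator seed points placed in the lumen (chord-length
  parameterization, arc-length resampling); the curve's arc length is the
  length of disease in cm.
- **Bowel-wall segmentation**, two ways:
  *manual* — validation of an operator mask against the wall-only
  convention (serosa to mucosa, lumen excluded);
  *semi-automated* — the ROI around the centerline is split into
  contiguous partitions (k-means on intensity + spatially weighted
  coordinates, then face-connected component splitting), each partition
  is described by a feature vector (intensity statistics, size, shape,
  centerline-relative geometry), and a random-forest regressor scores the
  probability that the partition belongs to the wall; partitions at or
  above threshold are assembled into the mask, with a hard geometric
  lumen exclusion.
- **Morphometry** — wall volume in mL (voxel count x voxel volume); wall
  thickness from per-slice 2D Euclidean distance transforms: at each
  medial ("central") pixel `m` of the wall cross-section the local
  thickness is `2 * EDT(m) - p` (`p` = in-plane pixel spacing), averaged
  into a mean and maximum wall thickness.
- **Longitudinal statistics** — mixed-effects change over time
  (fixed categorical timepoint + random subject intercept, REML,
  Satterthwaite joint F-test), percent change of the group mean from
  baseline `100 * (x_base - x_follow) / x_base`, ICC(2,1)
  absolute-agreement with F-based confidence interval for manual vs
  semi-automated volumes, and Pearson correlations with Fisher-z CIs.
- **Synthetic phantoms** — tubular bowel phantoms (bright lumen,
  intermediate thickened wall, dark background, configurable noise) on an
  anisotropic SSFSE-like grid (1.3 x 1.3 x 5 mm) with analytic ground
  truth for length, wall volume and thickness, plus longitudinal cohort
  simulators (measurement-level and phantom-level) with multiplicative
  treatment-response shrinkage.

No patient images ship with the package; every analysis runs on phantoms
with exact ground truth.

## Worked example

Simulate an inflamed segment, segment it semi-automatically, and measure
it:

```r
library(enterovol)

ph <- make_phantom(phantom_spec(lumen_radius_mm = 5,
                                wall_thickness_mm = 4, rng_seed = 42))
ph
#> <phantom> 72 x 72 x 32 voxels; truth: length 13.9 cm, wall volume 24.43 mL, mean thickness 4.0 mm

seeds <- centerline_from_truth(ph$truth, n_seeds = 10, jitter_mm = 1,
                               seed = 42)   # an imperfect operator
cl <- interpolate_centerline(seeds)
cl
#> <centerline> 288 points, length of disease 13.9 cm

model <- train_on_phantoms(n_phantoms = 30, rng_seed = 1)
seg <- semiauto_segment(ph$volume, cl, model, seed = 42)
seg
#> <semiauto_segmentation> 9/40 partitions included; volume 23.4 mL; lumen radius 5.0 mm
dice_coefficient(seg$mask, ph$truth$wall_mask)
#> [1] 0.977

measure_examination(seg$mask, cl)
#>   length_cm volume_mL mean_thickness_mm max_thickness_mm
#> 1      13.9      23.4               3.6              4.5
```

The segmenter recovers the 24.4 mL ground-truth wall to within ~1 mL
(Dice 0.98), the 13.9 cm length exactly at reporting precision, and the
4 mm wall to within half a pixel.

Longitudinal statistics on a simulated 20-subject cohort (three
timepoints, study-style missing visits):

```r
tab <- make_longitudinal_cohort(n_subjects = 20, missingness = "study",
                                rng_seed = 7)
run_study_analysis(tab)
#> <study_analysis> 20 subjects, 56 records
#> Change over time (mixed-effects joint timepoint test):
#>   max_thickness_mm     13.1 vs. 10.3 vs. 8.6   p = 0.004728
#>   ...
#>   manual_volume_mL     33.7 vs. 22.9 vs. 9.2   p = 6.105e-07
#> Percent change of the group mean from baseline:
#>   manual_volume_mL     42% (6 weeks), 79% (6 months)
#>   ...
#> Manual vs semi-automated volume: <icc_agreement> ICC(2,1) = 0.95 [95% CI: 0.60-0.98], excellent (n = 56)
```

Note the characteristic ordering: the volumetric percent change exceeds
either linear measurement's, because volume integrates wall thinning
*and* segment shortening.

A command-line front end over the same functions (subcommands
`simulate`, `length`, `segment`, `measure`, `stats`, each writing a JSON
run log) is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "enterovol.R", package = "enterovol"))') \
    simulate --seed 3 --out phantom/
```

## Package layout

- `R/phantom.R`, `R/phantom-cohort.R` — phantom generator and cohort
  simulators (ground truth, treatment-response shrinkage, operator-like
  mask perturbation)
- `R/volume.R` — `image_volume` / `seg_mask` containers, NIfTI-1 and
  seed-point I/O
- `R/centerline.R`, `R/geometry.R`, `src/` — centerline interpolation
  and length of disease
- `R/partition.R`, `R/segmentation.R` — partitioning, features,
  partition-scoring model, mask assembly and validation
- `R/morphometry.R` — volume, distance-transform thickness, Dice
- `R/stats.R`, `R/study.R`, `R/cohort.R` — longitudinal statistics and
  reporting
- `vignettes/enterovol-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations
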