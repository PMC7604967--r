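# mswmscore

Preoperative radiologic scoring for medial sphenoid wing meningiomas.

Medial sphenoid wing meningiomas sit against the cavernous sinus, the
anterior clinoid and the terminal internal carotid artery, and how much of a
tumor can be removed (the Simpson resection grade, I–IV) is largely decided
by four things visible on preoperative MRI/MRA: how big the tumor is, how far
it wraps around the major arteries (and whether it narrows them), whether it
has infiltrated the cavernous sinus, and whether it has invaded bone. This
package turns co-registered 3D label masks of those structures into a 1–10
point score and a predicted resection band, and ships the statistics used to
validate such a score on a cohort.

## The score

| Component | Levels | Points |
|---|---|---|
| Tumor volume | < 20 cm³ / 20–50 cm³ / > 50 cm³ | 1 / 2 / 3 |
| Arterial involvement | none | 0 |
| | any artery contacted (base) | 1 |
| | + any artery fully encircled | +1 |
| | + more than one artery involved | +1 |
| | + any involved artery narrowed (≥ 20% caliber loss) | +1 |
| Cavernous sinus infiltration | no / yes | 0 / 2 |
| Bone invasion | no / yes | 0 / 1 |

Totals run from 1 to 10 and map to a predicted resection band:
total < 4 → Simpson I, 4–7 → Simpson II, > 7 → Simpson III–IV.
The assessed arterial segments are C4, C5 (internal carotid), M1, M2
(middle cerebral) and A1, A2 (anterior cerebral).

## What the package does

- **Feature extraction** (`extract_features`): tumor volume from voxel
  counts; vessel centerlines from the artery masks (geodesic two-pass
  extraction); circumferential angular coverage of each artery by the tumor
  (radial probing in the plane perpendicular to the centerline); lumen
  narrowing from the local radius profile; cavernous sinus and bone overlap
  volumes against a 0.1 cm³ threshold.
- **Scoring** (`total_score`, `predict_resection_band`,
  `enumerate_score_space`): the table above, with configurable band cutoffs.
- **Cohort statistics** (`cohort_stats`): Kruskal–Wallis and chi-square tests
  by resection grade, proportional-odds adjusted odds ratios, Spearman
  correlations (mid-rank ties), linear discriminant classification accuracy,
  and score–outcome correlation.
- **Synthetic data** (`make_phantom`, `simulate_cohort`,
  `reconstruct_printed_cohort`): 3D phantoms whose every feature is known by
  construction, an ordinal cohort simulator, and an exact reconstruction of
  the published 46-patient cohort's component table.
- **I/O and pipeline** (`read_segmentation_set`, `run_pipeline`,
  `inst/cli/mswm-tool`): NIfTI masks (per-structure or one multi-label
  bitmask volume), cohort CSVs, JSON configs and run reports, and a thin
  command-line tool over all of it.

## Worked example

```r
library(mswmscore)

# A synthetic scene: a tumor collar fully encircling and narrowing M1,
# plus 150 voxels of cavernous sinus infiltration.
art <- artery_spec("M1", rbind(c(30, 30, 10), c(30, 30, 50)),
                   narrowing_fraction = 0.3)
ph <- make_phantom(phantom_spec(grid_shape = c(60, 60, 60),
                                tumor_kind = "annular_wrap",
                                wrap_angle_deg = 360, arteries = list(art),
                                cs_overlap_voxels = 150, seed = 7))

f <- extract_features(ph$seg)
f
#> <radiologic_features> volume 3.02 cm3 (grade 1) | arterial 3 | CS TRUE | bone FALSE
#>   M1: coverage 360 deg, encircled, narrowed

total_score(f)
#> <score_result> total 6 (volume 1 + arterial 3 + CS 2 + bone 0) -> SimpsonII
```

Cohort side:

```r
co <- reconstruct_printed_cohort()   # the published 46-patient component table
d <- descriptive_summary(co)
round(c(d$score_mean, d$score_sd), 1)
#> [1] 5.3 2.8

count_percent(printed_simpson_counts())
#>   level  n percent
#> 1     I 10    21.7
#> 2    II 17    37.0
#> 3   III 15    32.6
#> 4    IV  4     8.7
```

## Reproducing results

`scripts/acceptance.R` computes the acceptance targets at runtime from the
installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The command-line tool is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mswm-tool", package = "mswmscore"))')
Rscript "$CLI" phantom --wrap-deg 360 --seed 2 --out ph1
Rscript "$CLI" score --in ph1
Rscript "$CLI" simulate-cohort --n 60 --seed 3 --out cohort.csv
Rscript "$CLI" cohort-stats --in cohort.csv
Rscript "$CLI" run --seg ph1 --cohort cohort.csv --out report.json
```

See `vignettes/scoring-methods.Rmd` for the methods: how each feature is
measured, why each default threshold is what it is, what the phantoms do and
do not emulate, and the package's design decisions and limitations.
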