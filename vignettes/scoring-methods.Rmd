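---
title: "Methods: preoperative resection scoring from 3D label masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preoperative resection scoring from 3D label masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mswmscore)
```

This vignette documents how every number the package reports is computed:
the geometric measurements behind the four score components, the defaults
and why they are what they are, what the synthetic generators emulate (and
deliberately do not), and the main design decisions and limitations.

## 1. The scoring model

A patient is summarized by four radiologic components measured from
co-registered 3D label masks (tumor; arterial segments C4, C5, M1, M2, A1,
A2; cavernous sinus; bone):

* **Volume grade** (1–3): tumor volume below 20 cm³, between 20 and 50 cm³
  (inclusive on both ends), or above 50 cm³.
* **Arterial involvement score** (0–4): 0 if no artery is involved,
  otherwise 1 base point plus one point each for *any artery fully
  encircled*, *more than one artery involved*, and *any involved artery
  narrowed*. Each criterion contributes at most one point regardless of how
  many arteries exhibit it.
* **Cavernous sinus infiltration** (0 or 2 points).
* **Bone invasion** (0 or 1 point).

The total runs over the integers 1–10 (`enumerate_score_space()` lists all
60 component combinations) and maps to a predicted resection band:
total < 4 → Simpson I, 4–7 → Simpson II, > 7 → Simpson III–IV. The two
cutoffs are configurable (`pipeline_config(band_cutoffs = ...)`); the
defaults are the published ones.

## 2. Geometric measurements

All geometry is axis-aligned voxel geometry: the physical coordinate of
voxel index `i` along an axis with spacing `s` is `(i - 1) * s` mm. No
affine or orientation handling is attempted; inputs are assumed
co-registered and consistently oriented, and mismatched shapes or spacings
are hard errors at read time.

**Tumor volume** is the voxel count times the voxel volume. On phantoms
with analytically known volume this converges to within about 2% at 0.5 mm
spacing for centimeter-scale objects, which is far inside the 20/50 cm³
grading boundaries for any realistic tumor.

**Vessel centerlines** are extracted in two passes. Artery voxels form a
26-connected graph (single connected component required; anything else is
rejected as "not a tube"). A geodesic double sweep finds the two ends; arc
length along the geodesic is binned (bin width 1.5 × the largest spacing)
and bin centroids form a provisional polyline, smoothed by two passes of a
window-3 moving average. In the second pass all voxels are re-projected
onto this polyline and re-binned, which removes the slab-tilt bias a single
geodesic pass suffers on curved vessels. The local radius per bin is the
maximum projection distance of its voxels (end-clamped projections
excluded, since voxels projecting obliquely onto the polyline ends would
inflate the radius). Points whose arc-length position is within one median
radius of either end are flagged non-`interior`; end caps bias the radius
profile low and are excluded from narrowing detection. On a 1 mm straight
cylinder of radius 3 mm the interior radius profile is recovered within
half a voxel, and on a quarter torus the arc length is recovered within 5%.

**Angular coverage** (encasement) is measured per centerline point: 360
one-degree angular bins in the plane perpendicular to the local tangent,
each probed radially from the local vessel surface outward through a 2 mm
band (`probe_band_mm`) in 0.4 mm steps, reading the containing voxel of the
tumor mask. A bin counts as covered if any probe point hits tumor; the
artery's coverage is the maximum over centerline points of the covered-bin
count. The 2 mm band operationalizes "tumor at the vessel wall": deep
enough to tolerate a sub-voxel misalignment between masks, shallow enough
not to pick up tumor merely near the vessel.

An artery is *involved* if its coverage is positive, and *fully encircled*
if coverage reaches `full_encirclement_deg` (default 355°, not 360°: a
rasterized full wrap can lose a single 1° bin to voxelization, and 355°
has no clinical difference from complete encirclement).

The angular resolution of any coverage measurement on voxel data is
limited by the angular subtense of one voxel at the vessel surface —
about `2 * asin(spacing / (2 * radius))`, i.e. roughly 19° for a 3 mm
vessel at 1 mm spacing. Validation against phantoms therefore uses a
tolerance of 10° (centerline and frame estimation budget) plus this
subtense, rather than pretending sub-voxel angular accuracy.

**Narrowing** compares, over `interior` centerline points only, the minimum
local radius to the median: a relative reduction of at least
`narrowing_delta` (default 0.20) counts as narrowed. The 20% default is the
smallest caliber loss that is reliably distinguishable from voxelization
noise at typical (≈1 mm) spacing for 3 mm vessels, and matches the
phantom generator's convention for ground-truth narrowing. Fewer than 5
interior points is an "insufficient geometry" error, not a silent FALSE.

**Cavernous sinus infiltration and bone invasion** are overlap calls:
the tumor–structure overlap volume must strictly exceed `tau_cs_cm3` /
`tau_bone_cm3` (default 0.1 cm³ ≈ 100 voxels at 1 mm). A strict threshold
makes a handful of boundary voxels from imperfect segmentation
insufficient to flip a 2-point component; mere adjacency never counts.
The realized overlap is attached to the result for audit.

## 3. Synthetic data

### Phantoms

`make_phantom()` builds small co-registered scenes whose features are known
by construction — they emulate the *geometry* the measurement pipeline must
handle (wrap angle, narrowing, overlap), not imaging physics: there is no
noise, bias field, partial-volume effect, or registration error. Their role
is measurement validation, not realism.

* Arteries are tubes rasterized around polyline control points, with an
  optional smooth cosine narrowing dip (to `radius * (1 - fraction)`) over
  a chosen arc-length span (default the central 30%).
* `annular_wrap` tumors are collars in the radial band
  `[radius, radius + 4 mm]` around an artery, spanning exactly the
  requested `wrap_angle_deg` of circumference over the central 60% of the
  vessel — the ground-truth encasement angle.
* `ellipsoid` tumors have analytic volume `4/3 π a b c`.
* Cavernous sinus overlap is constructed to an exact voxel count;
  the bone slab is routed through the tumor's lower extent only when
  `bone_contact = TRUE`.
* The seed jitters the whole scene by a sub-voxel offset (all structures
  together), exercising voxelization robustness without changing truth.

Typical grids are 48–160 voxels per axis at 1 mm; tests run in seconds on
one CPU.

### Cohorts

Two generators exist because they answer different questions.

`reconstruct_printed_cohort()` returns the published 46-patient cohort as a
patient-level table. The publication reports only the *marginal* counts of
each component and of the total score; those marginals admit a joint
patient-level completion, and one exact completion (found once by integer
programming and frozen as a constant) is shipped. Every published marginal
— the score histogram, component counts, mean 5.3 ± 2.8 — is reproduced
exactly, and each row's components sum to its total. The completion is not
claimed to be the true patient-level data (it is generally not unique);
outcome columns are therefore `NA`, and only marginal statistics should be
read from it.

`simulate_cohort()` is a proportional-odds testing device: total scores are
drawn from a categorical distribution over 1–10 (default: the published
histogram), Simpson grade I–IV from a cumulative-logit model
`P(G ≤ k | s) = plogis(threshold_k − beta_score · s)` (defaults
`beta_score = 1`, thresholds 4.0, 5.7, 7.7), and the 4-level postoperative
outcome from an analogous model with a negative slope (worse outcomes at
higher scores). Components are then sampled uniformly among the
combinations consistent with each total. Because the generator *is* the
model that `adjusted_odds_ratios()` fits, parameter recovery is a sharp
correctness test of the statistics battery: at n = 2000 the mean recovered
log-OR is within a fraction of a percent of the generating value. The
defaults were calibrated once to the published descriptives and are study
conditions, not tuning knobs.

## 4. Statistics

* Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`) for ordinal
  variables across resection-grade groups; a variable constant across all
  patients is reported as statistic 0, p = 1 (the tie-corrected statistic
  is 0/0 there).
* Pearson chi-square without continuity correction
  (`stats::chisq.test(correct = FALSE)`) for the binary components.
* Spearman correlation as Pearson correlation of mid-ranks, with the
  large-sample t approximation for the p-value; verified against an
  independent mid-rank oracle to 1e-10 on tied data.
* Adjusted odds ratios from a proportional-odds fit (`MASS::polr`,
  Wald 95% CIs); this matches reporting a single OR per predictor for a
  4-level outcome. A binary (grade I–II vs III–IV) logistic fit is
  available as a sensitivity analysis. Separation is flagged (SE > 10),
  not silently reported.
* Linear discriminant classification accuracy (`MASS::lda`),
  resubstitution by default to match how such accuracies are usually
  reported, with leave-one-out as an honest alternative.

## 5. Design decisions and limitations

* **Build vs buy**: standard statistics and formats come from established
  packages (MASS, stats, RNifti, igraph, jsonlite); the scoring system,
  phantom rasterization, centerline extraction and angular-coverage
  measurement are the point of the package and are implemented here.
* **Multi-label NIfTI** uses bitmask voxel values (tumor = 1, CS = 2,
  bone = 4, arteries 8–256) so overlapping structures (tumor infiltrating
  CS or bone) round-trip exactly through a single volume.
* **Disjointness**: artery masks must be pairwise disjoint and disjoint
  from the tumor; CS and bone may overlap the tumor — that overlap is the
  infiltration signal itself.
* Voxel masks are trusted as given: no registration, no orientation
  handling, no segmentation of raw images.
* The angular-coverage resolution floor (one voxel's subtense at the
  vessel surface) means wrap angles are only meaningful to ~10–20° at 1 mm
  spacing for 3 mm vessels; finer claims need finer masks.
* The printed-cohort completion supports marginal statistics only; any
  joint statistic computed from it reflects one feasible completion, not
  the study data.
* The simulator draws components uniformly among combinations consistent
  with each total; real component correlations beyond what the total
  implies are not modeled.

## 6. A minimal end-to-end run

```{r example}
art <- artery_spec("M1", rbind(c(30, 30, 10), c(30, 30, 50)),
                   narrowing_fraction = 0.3)
ph <- make_phantom(phantom_spec(grid_shape = c(60, 60, 60),
                                tumor_kind = "annular_wrap",
                                wrap_angle_deg = 360, arteries = list(art),
                                cs_overlap_voxels = 150, seed = 7))
f <- extract_features(ph$seg)
f
total_score(f)
```

```{r cohort}
co <- simulate_cohort(cohort_model(n_patients = 120, seed = 1))
st <- cohort_stats(co)
st$spearman
st$discriminant_accuracy
```
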