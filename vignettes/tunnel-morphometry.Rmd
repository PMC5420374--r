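---
title: "Bone-tunnel morphometry and widening analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-tunnel morphometry and widening analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acltunnel)
```

`acltunnel` measures drilled graft tunnels in ACL-reconstructed knees
from segmented CT label volumes and analyses their widening between an
immediately post-operative scan (Year 0) and a one-year follow-up
(Year 1). This vignette documents the models, the tunable parameters,
the design decisions that were genuinely open, and what the synthetic
phantoms do and do not establish about real data.

## Coordinate conventions

All geometry is computed in world millimetre coordinates. Voxel index
`(i, j, k)` (1-based) maps to the world-space centre
`origin + (index - 1) * spacing`, so anisotropic spacing — clinically,
fine in-plane resolution with 1.5 mm slices — is handled once, at the
mask-to-points conversion, and every fit downstream is grid-agnostic.

The joint line is a plane whose normal points *into* bone. A tunnel's
axial coordinate is 0 where the (fitted) tunnel axis crosses this plane
and grows with depth. "Aperture" is not defined numerically in the
clinical workflow this package mirrors; we define it as axial
coordinate 0. This is one of two interpretation choices flagged below.

## The measurement model

A segmented tunnel is converted to boundary points by one of two
methods:

* **voxel faces** (default): centres of exposed voxel faces, with the
  outward face normal recorded. Unbiased on average for cylindrical
  walls (face centres straddle the true surface) and exact about where
  mask voxels end.
* **isosurface**: 0.5-level crossings of a 3×3×3 box-smoothed binary
  field, linearly interpolated along grid edges, with normals from the
  smoothed gradient. Smoother, but it erodes *open ends* (the field is
  smoothed against the empty joint space), so the default for aperture
  work is the face method. The two methods agree on cylinder radii to
  better than 0.1 mm at default spacing.

The **best-fit cylinder** minimises the sum of squared radial residuals
over the five intrinsic parameters (two for the axis direction, two for
the axis point, one for the radius). The axis starts at the first
principal component of the cloud and is refined by Levenberg–Marquardt
(`minpack.lm`); parameter tolerances are 1e-14 with at most 100
iterations, and exact data are recovered to ~1e-10 mm. Fits whose RMS
residual exceeds 20% of the radius are rejected as degenerate: voxelised
tunnels sit near 3% and a sphere — the canonical non-cylinder — near
28%, so the threshold separates the two regimes by an order of
magnitude on each side.

**Cross-section circles** at the aperture and at 10.0 mm are fitted to
the points of a slab (default half-width 1.0 mm, on the order of one
slice) projected onto the plane through that axial position
perpendicular to the cylinder axis: a Kåsa algebraic fit initialises a
geometric Gauss–Newton refinement. Two robustness layers precede the
fit:

1. **Cap exclusion.** A voxelised tunnel's boundary includes its end
   caps, whose face centres lie across the whole cross-section rather
   than on the rim. Points whose outward normal points against the
   axis (dot product < -0.3) are dropped; for the six grid-aligned face
   normals this removes exactly the joint-facing cap faces.
2. **Prior-anchored trimming.** Starting from the cylinder fit (centre
   on the axis, cylinder radius), points with two-sided radial
   residuals beyond 3.5 MADs are trimmed over up to four rounds. On
   exact data the MAD collapses to zero and nothing is trimmed.

The full pipeline (`measure_tunnel()`) additionally trims the point set
along the axis before the *cylinder* fit, with an end margin of
`r·tan(θ) + half voxel diagonal` (θ = angle between the preliminary axis
and the joint normal) so end caps never enter the cylinder
least-squares problem; the circle fits then run on the untrimmed points
so the aperture slab stays populated. Screw filtering (below) runs
between trimming and fitting.

Two interpretation choices could not be settled from the described
clinical workflow and are implemented as stated, deliberately:

* cross-sections are taken **perpendicular to the cylinder axis**, not
  parallel to the anatomical joint surface — the 10.0 mm measurement is
  anchored to the cylinder axis, and perpendicular sections make the
  aperture and 10-mm values commensurable;
* the aperture plane passes through the axis/joint-plane intersection.

For near-perpendicular tunnels the two conventions coincide; for very
oblique tunnels a joint-parallel aperture circle would read higher
(elliptical section).

## Screw-artifact filtering

Tibial interference screws can protrude diagonally from the tunnel
wall. The manual workflow draws a line along the wall and excludes the
screw tip; the reproducible surrogate here is iterative robust
rejection: fit a cylinder, compute radial residuals, drop points more
than `k_mad` (default 3.5) MADs *above* the median residual, refit;
stop at convergence or `max_iter` (default 5). Only outward outliers
are removed, so noise-free artifact-free cylinders pass through
untouched, and removing more than 40% of points aborts with an error —
at that point the object is not a tunnel. On phantoms with a 2 mm
screw-tip lobe the naive fit reads ~0.1 mm high while the filtered fit
is within 0.02 mm of truth.

## Communication detection

Double-bundle tunnel pairs converge toward the joint; "communication"
means the separating cortical ridge is absent at the joint line. The
detector bins depth (along the joint normal) at one slice thickness and
computes, per bin, the minimum *bone gap* between the two masks: the
smallest voxel-centre distance minus the voxel extent projected on the
connecting direction, so face- or corner-adjacent (or overlapping)
voxels score gap ≤ 0 ("contact"). Communication is contact in the bin
at the joint line. The ridge distance is the zero crossing of the gap
profile, interpolated between the depths of the minimising voxel pairs
(not the bin centres — the minimising pair sits at a bin's shallow
edge, and using its true depth removes a half-bin bias). On constructed
pairs with ridge depths spanning 2.7–15.2 mm the estimate is within one
slice thickness (1.5 mm) of truth with correct ordering.

## The statistical layer

* **Widening.** Per subject and tunnel, `Δ = d₁ − d₀` in mm and
  `100·Δ/d₀` in percent. Reports average the per-subject percentages
  (confidence intervals on percentages imply subject-level values); the
  ratio-of-means variant `100·mean(Δ)/mean(d₀)` is also provided, and
  both reproduce the integer percentages a study report would print
  (e.g. 1.4/8.3 → 17%).
* **Tests.** Paired t within technique; Welch t between techniques
  (Welch–Satterthwaite df; it reduces to Student's t exactly when
  variances and group sizes are equal). Raw p-values at α = 0.05, with
  an optional Holm adjustment flag; p ≥ α is printed as "ns", exact
  values are kept in machine output.
* **Reliability.** ICC(2,1) — single measures, absolute agreement,
  two-way random effects — from the ANOVA decomposition
  `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)`. Absolute
  agreement means a constant rater offset lowers the coefficient; the
  3×2 matrix `[[1,2],[2,3],[3,4]]` gives exactly 2/3 and is kept as a
  hand-checkable test. Confidence intervals are nonparametric
  bootstrap: subjects (rows) resampled with replacement, B = 2000 by
  default, percentile 2.5/97.5 interval, seeded. Percentile intervals
  undercover slightly at small n; at the default 15-subject, 3-rater
  design the measured coverage over 500 simulated studies is 90% at
  nominal 95%, which we accept and document rather than switch to a
  less transparent interval. Whether the sampling unit is the subject
  or the tunnel is selectable; subject is the default.
* **Power.** The a priori sample size iterates n over the exact
  noncentral-t power of a two-sided one-sample t-test on paired
  differences — the test behind the design calculation is not named in
  the clinical literature this mirrors, so the paired-difference t is a
  documented assumption, with a normal-approximation cross-check. For
  Δ = 0.5 mm, SD = 0.74 mm, α = 0.05, power 0.80 the answer is n = 20.
  Note that for very large effects the exact criterion still needs
  n = 3 at Δ = 10·SD (the df = 1 critical value is 12.7); n = 2 is
  reached only for still larger effects, which is the correct
  noncentral-t behaviour.

## The synthetic phantom: what it emulates, and what it does not

The generator reproduces the statistical and geometric structure the
analysis relies on:

* anisotropic CT-like grids — default 96×96×40 voxels at
  0.4×0.4×1.5 mm, preserving clinical slice thickness and anisotropy at
  desk scale (a full 512×512 in-plane grid is a config change);
* drilled constant-radius Year-0 tunnels; AM/PL drill minima (6.0 /
  5.0 mm) enforced as in the hamstring-graft inclusion criteria;
* widening profiles: **uniform**, and **aperture-weighted** — clinical
  data show more widening at the aperture than at 10 mm
  (windshield-wiper effect) but no functional form; we chose a linear
  decay from the full radius increase at depth 0 to half of it at
  10 mm (constants configurable) for analysability;
* cohorts: per subject and tunnel type, Year-0 diameter
  ~ Normal(μ₀, σ₀) truncated above 4 mm and widening ~ Normal(μΔ, σΔ)
  truncated at −0.5 mm; defaults are the best-fit-cylinder means/SDs of
  a 20 DB + 22 SB hamstring-graft cohort. Year-0 truncation is
  essentially never active (worst case P < 1e-4); widening truncation
  is active for the wider SDs (up to ~10% of draws) and is part of the
  model — tunnels do not shrink appreciably. The correlation between
  Year-0 size and widening is 0 by default (no data to set it);
* screw-tip lobes (sphere unioned near the distal end), slice-wise
  rater perturbations (in-plane signed-distance re-threshold with a
  mean outward bias and per-voxel Gaussian jitter — matching how
  slice-by-slice manual edits behave), and converging tunnel pairs
  whose entry separation and divergence half-angle are solved for a
  requested ridge depth.

In **fast mode** the cohort is analytic (no voxelisation): the drawn
widening is the cylinder-level value and the three measurement levels
follow from the chosen profile. This is what the statistics-layer tests
use; geometry-layer tests always run on voxel phantoms. One
consequence: level-specific effect sizes (e.g. a non-significant 10-mm
row for one tunnel type alongside significant cylinder rows, as real
cohorts can show) cannot arise from the two-parameter-per-tunnel
generator; emulating that would need per-level parameters, which we
considered out of proportion for the package's purpose.

The phantoms deliberately omit bone texture, trabecular structure,
metal artifacts and DICOM semantics. Passing the test suite therefore
shows that the *measurement and inference chain* is correct and
calibrated on geometry with known truth at clinical voxel sizes — not
that segmentation of real, artifact-laden CT data is solved; on real
data the segmentation quality and the per-case trim windows dominate
the error budget.

## Problem sizes and numerical choices

The seeded test suite uses 50 voxelised phantoms (diameters 5–10 mm,
tilts up to 25°) for geometry recovery — mean absolute cylinder-diameter
error ≤ 0.2 mm, observed ~0.03 mm — and 10,000 simulated cohorts each
for the type-I error (5% ± 1% at n = 20) and power (observed ~0.82 at
the design point, consistent with n = 20) checks. Bootstrap
reproducibility is bit-exact for a fixed seed. Geometry is always
deterministic: the phantom seed affects intensity noise only, never
masks or ground truth.

Degenerate inputs error loudly rather than fall back silently: coplanar
or spherical clouds, empty threshold selections, slabs with fewer than
8 rim points, masks split by a perturbation, tunnels exiting the grid,
widenings that would make a radius non-positive, ICC matrices with
missing cells.

## Known limitations

* The aperture convention (perpendicular section at the axis–plane
  intersection) is an interpretation; joint-parallel aperture sections
  would read systematically higher for oblique tunnels.
* The isosurface point method erodes open tunnel ends; use the default
  face method for aperture measurements.
* Ridge-distance estimates are slice-quantised; sub-slice accuracy
  would need a finer depth binning than the acquisition supports.
* Fast-mode cohorts share one widening draw across measurement levels
  (scaled by the profile), so cross-level noise correlations are 1 by
  construction; voxel mode breaks this but costs ~0.5 s per tunnel.
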