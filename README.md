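# acltunnel

Semi-automated 3D CT morphometry of bone tunnels in ACL-reconstructed
knees, in R.

After anterior cruciate ligament (ACL) reconstruction, the drilled graft
tunnels in femur and tibia enlarge during the first post-operative year
("tunnel widening"). The amount of widening matters for revision surgery:
it is bone loss next to the joint, and large defects need staged bone
grafting. `acltunnel` implements the measurement and analysis layer of a
CT-based widening study as reproducible code:

* **Geometry.** A segmented tunnel is reduced to a point cloud and
  summarised by a least-squares **best-fit cylinder** (axis `a`, radius
  `r`, minimising `Σᵢ (dist(pᵢ, a) − r)²`) and by **best-fit circles** of
  the cross-section at the tunnel **aperture** (where the cylinder axis
  crosses the joint line) and **10.0 mm** deeper along the axis. Each
  primitive reports diameter and cross-sectional area `CSA = π r²`.
  Protruding interference-screw tips are removed by iterative robust
  (MAD-based) residual rejection before fitting.
* **Communication.** Converging double-bundle tunnel pairs are checked
  for a missing cortical ridge at the joint line; when they communicate,
  the depth at which separating bone first appears is estimated from a
  per-slice minimum bone-gap profile.
* **Statistics.** Per-subject widening `Δ = d₁ − d₀` (mm and %), paired
  t-tests within technique, Welch t-tests between single-bundle (SB) and
  double-bundle (DB) groups, inter-/intra-rater reliability as the
  single-measures absolute-agreement intraclass correlation ICC(2,1)
  with nonparametric (subject-resampling) bootstrap CIs, and a priori
  power / sample-size for paired designs via the noncentral t
  distribution.
* **Synthetic phantoms.** Since patient CTs are not public, the package
  ships a ground-truthed phantom generator: drilled near-cylindrical
  tunnels on anisotropic CT-like voxel grids (0.4 × 0.4 × 1.5 mm by
  default), uniform or aperture-weighted widening between timepoints,
  screw-tip artifacts, slice-wise rater perturbations, and converging
  tunnel pairs with a controllable cortical-ridge depth. Every test runs
  against known ground truth.

## Worked example

```r
library(acltunnel)

# a ground-truthed phantom: 8.3 mm femoral tunnel, widened 1.7 mm at the
# aperture decaying to 0.85 mm deeper in bone
jp <- joint_plane(c(0, 0, 6), c(0, 0, 1))
t0 <- tunnel_spec(c(19, 19, 6), c(0, 0, 1), diameter = 8.4, length = 30)
t1 <- widen_tunnel(t0, 1.7, "aperture_weighted")
ph <- generate_phantom(phantom_spec(), list(t1), seed = 1)

measure_tunnel(mask_to_points(ph$masks[[1]]), jp)
#> <tunnel_measurement> femur/SB
#>   cylinder: 9.42 mm (69.7 mm^2)
#>   aperture: 10.08 mm (79.8 mm^2)
#>   at 10 mm: 9.32 mm (68.3 mm^2)
```

The ground truth is 10.1 mm at the aperture and 9.25 mm at 10 mm: the
pipeline recovers both to well under a tenth of a millimetre at clinical
voxel sizes, and reproduces the aperture-dominant widening pattern
(the "windshield-wiper" effect).

A full simulated study — 42 subjects (20 DB, 22 SB), paired Year-0 /
Year-1 measurements — and its analysis:

```r
coh <- generate_cohort(cohort_spec(seed = 1))
rep <- cohort_report(coh)
dplyr::filter(rep$widening, level == "cylinder")[
  , c("group", "tunnel", "n", "widening_mm", "widening_pct", "p_label")]
#>   group   tunnel  n widening_mm widening_pct p_label
#> 1    DB femur_AM 20       0.489            7  <0.001
#> 2    DB femur_PL 20       1.028           18  <0.001
#> 3    DB tibia_AM 20       0.922           10  <0.001
#> 4    DB tibia_PL 20       0.358            5   0.007
#> 5    SB    femur 22       1.368           16  <0.001
#> 6    SB    tibia 22       1.242           12  <0.001

required_sample_size(delta = 0.5, sd = 0.74, alpha = 0.05, power = 0.80)
#> [1] 20
```

Each tunnel widens significantly, the SB femoral tunnel widens most, and
20 patients suffice to detect a 0.5 mm mean widening with 80% power when
the paired-difference SD is 0.74 mm — the design calculation behind a
20-subject DB arm.

Reliability of repeated measurements:

```r
m <- simulate_rater_measurements(15, k_raters = 3, seed = 4)
bootstrap_icc_ci(m, B = 2000, seed = 9)
#> <icc_result> ICC(2,1) = 0.836 (15 subjects, 3 raters)
#>   bootstrap 95% CI [0.594, 0.914] (B = 2000, seed 9)
```

## Command line

A thin CLI over the same functions lives at `inst/cli/acltunnel.R`:

```sh
Rscript inst/cli/acltunnel.R simulate --config cfg.yaml
Rscript inst/cli/acltunnel.R measure  --config cfg.yaml --masks 'run/*.nii.gz' --out meas.csv
Rscript inst/cli/acltunnel.R analyze  --config cfg.yaml --measurements meas.csv --out results/
```

Every output embeds the config hash and seed; a fixed config reproduces
byte-identical reports.
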