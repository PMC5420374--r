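test_that("a perpendicular drilled tunnel has the analytic cross-section in every slice", {
  ph <- perp_phantom(diameter = 8, length = 30)
  mask <- ph$masks[[1]]
  vox_area <- prod(mask$spacing[1:2])
  slices <- which(apply(mask$voxels, 3, any))
  # drop the deepest slice, which the tunnel end may only partially cover
  for (k in head(slices, -1)) {
    area <- sum(mask$voxels[, , k]) * vox_area
    expect_lt(abs(area - pi * 16), 2 * pi * 4 * mask$spacing[1])  # one boundary ring
  }
  expect_equal(ph$truth$diameter_aperture, 8)
  expect_equal(ph$truth$diameter_at10, 8)
  expect_equal(ph$truth$diameter_cylinder, 8)
})

test_that("geometry is deterministic: the seed only touches intensity noise", {
  ph1 <- perp_phantom(seed = 1)
  ph2 <- perp_phantom(seed = 999)
  expect_identical(ph1$masks[[1]]$voxels, ph2$masks[[1]]$voxels)
  expect_identical(ph1$truth, ph2$truth)
  expect_false(identical(ph1$volume$voxels, ph2$volume$voxels))
  # same seed reproduces intensities bit for bit
  ph3 <- perp_phantom(seed = 1)
  expect_identical(ph1$volume$voxels, ph3$volume$voxels)
})

test_that("an oblique tunnel keeps its true diameter while the slice footprint is elliptical", {
  ph <- oblique_phantom(diameter = 8, tilt_deg = 30)
  expect_equal(ph$truth$diameter_cylinder, 8)
  mask <- ph$masks[[1]]
  # mid-depth slice: minor axis (perpendicular to tilt) ~ 8 mm,
  # major axis (along tilt, x here) ~ 8 / cos(30 deg) ~ 9.24 mm
  ks <- which(apply(mask$voxels, 3, any))
  k <- ks[ceiling(length(ks) / 2)]
  sl <- mask$voxels[, , k]
  minor <- max(apply(sl, 1, sum)) * mask$spacing[2]
  major <- max(apply(sl, 2, sum)) * mask$spacing[1]
  expect_lt(abs(minor - 8), 2 * mask$spacing[2])
  expect_lt(abs(major - 8 / cos(pi / 6)), 2 * mask$spacing[1])
})

test_that("tunnels that exit the grid are rejected with a message", {
  spec <- phantom_spec(grid_shape = c(32, 32, 20))
  too_long <- tunnel_spec(c(6.2, 6.2, 6), c(1, 0, 0.2), diameter = 8, length = 40)
  expect_error(generate_phantom(spec, list(too_long)), "exits the phantom grid")
})

test_that("overlapping tunnels warn unless flagged as a communicating pair", {
  spec <- phantom_spec()
  t1 <- tunnel_spec(c(17, 19, 6), c(0, 0, 1), diameter = 8, length = 20)
  t2 <- tunnel_spec(c(21, 19, 6), c(0, 0, 1), diameter = 8, length = 20)
  expect_warning(generate_phantom(spec, list(t1, t2)), "overlap")
  expect_no_warning(generate_phantom(spec, list(t1, t2), expect_overlap = TRUE))
})

test_that("widen_tunnel applies uniform and aperture-weighted profiles exactly", {
  t0 <- perp_tunnel(diameter = 8)
  tu <- widen_tunnel(t0, 0.8, "uniform")
  a <- seq(0, 30, by = 1)
  expect_equal(2 * tu$radius_profile(a), rep(8.8, length(a)))

  t_id <- widen_tunnel(t0, 0, "aperture_weighted")
  expect_equal(2 * t_id$radius_profile(a), rep(8, length(a)))

  taw <- widen_tunnel(perp_tunnel(diameter = 8.4), 1.7, "aperture_weighted")
  expect_equal(2 * taw$radius_profile(0), 10.1)
  expect_equal(2 * taw$radius_profile(10), 9.25)
  expect_equal(2 * taw$radius_profile(20), 9.25)  # constant beyond decay depth

  expect_error(widen_tunnel(perp_tunnel(diameter = 5), -6, "uniform"),
               "non-positive")
})

test_that("drill diameters respect the hamstring graft minima", {
  expect_error(tunnel_spec(c(0, 0, 6), c(0, 0, 1), diameter = 4.5,
                           bundle = "PL"), "5.0 mm")
  expect_error(tunnel_spec(c(0, 0, 6), c(0, 0, 1), diameter = 5.5,
                           bundle = "AM"), "6.0 mm")
  expect_s3_class(tunnel_spec(c(0, 0, 6), c(0, 0, 1), diameter = 5.0,
                              bundle = "PL"), "tunnel_spec")
})

test_that("screw artifacts grow the mask laterally; degenerate cases are no-ops or errors", {
  ph <- perp_phantom(diameter = 8, length = 30, side = "tibia",
                     bundle = "SB")
  m0 <- ph$masks[[1]]
  expect_identical(add_screw_artifact(m0, c(4.5, 0, -2), 0), m0)
  # a lobe fully inside the tunnel is a no-op
  inside <- add_screw_artifact(m0, c(0, 0, -5), 1.5, joint_plane = jp_default())
  expect_identical(inside$voxels, m0$voxels)
  # a real lobe adds voxels
  lobed <- add_screw_artifact(m0, c(4.5, 0, -2), 2, joint_plane = jp_default())
  expect_gt(sum(lobed$voxels), sum(m0$voxels))
  # a sphere far from the wall is disconnected
  expect_error(add_screw_artifact(m0, c(12, 0, -5), 1.5,
                                  joint_plane = jp_default()),
               "disconnected")
})

test_that("rater perturbation dilates by the bias and is seed-deterministic", {
  ph <- perp_phantom(diameter = 8, length = 30)
  m0 <- ph$masks[[1]]
  expect_identical(perturb_segmentation(m0, 0, 0, seed = 1), m0)

  dilated <- perturb_segmentation(m0, rater_bias_mm = 0.2, seed = 1)
  m <- measure_tunnel(mask_to_points(dilated), jp_default())
  # the slice-wise re-threshold quantises the boundary shift at the voxel
  # scale, so the fitted diameter matches the nominal dilation to within
  # half the in-plane voxel diagonal
  expect_lt(abs(m$cylinder$diameter - 8.4), sqrt(2) * 0.4 / 2)
  expect_gt(m$cylinder$diameter, 8.1)  # strictly dilated

  a <- perturb_segmentation(m0, 0.1, 0.15, seed = 7)
  b <- perturb_segmentation(m0, 0.1, 0.15, seed = 7)
  c <- perturb_segmentation(m0, 0.1, 0.15, seed = 8)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("two noisy raters of the same subjects give highly concordant fitted diameters", {
  # small Monte Carlo with the downstream ICC: subject diameters differ,
  # rater noise is boundary jitter only
  diams <- seq(5.5, 9.5, length.out = 6)
  meas <- sapply(1:2, function(r) {
    sapply(seq_along(diams), function(i) {
      ph <- perp_phantom(diameter = diams[i], length = 24)
      pm <- perturb_segmentation(ph$masks[[1]], 0, 0.15, seed = 100 * r + i)
      measure_tunnel(mask_to_points(pm), jp_default())$cylinder$diameter
    })
  })
  expect_gt(icc_2_1(meas)$icc, 0.9)
})

test_that("generated cohorts match the requested moments and truncation is benign", {
  cs <- cohort_spec(seed = 5)
  coh <- generate_cohort(cs)
  expect_equal(dplyr::n_distinct(coh$subject), 42)
  expect_equal(nrow(dplyr::distinct(coh, subject, group)) , 42)
  counts <- dplyr::count(dplyr::distinct(coh, subject, group), group)
  expect_equal(counts$n[counts$group == "DB"], 20)
  expect_equal(counts$n[counts$group == "SB"], 22)
  # DB subjects have 4 tunnels, SB 2; 3 levels x 2 timepoints each
  expect_equal(nrow(coh), (20 * 4 + 22 * 2) * 3 * 2)

  # zero-variance cohort reproduces the configured means exactly
  p0 <- default_widening_params()
  p0$d0_sd <- 0
  p0$dw_sd <- 0
  coh0 <- generate_cohort(cohort_spec(params = p0, seed = 1))
  truth0 <- attr(coh0, "truth")
  by_tun <- dplyr::summarise(dplyr::group_by(truth0, tunnel),
                             d0 = mean(d0), dw = mean(dw))
  ref <- dplyr::arrange(p0, tunnel)
  expect_equal(by_tun$d0, ref$d0_mean, tolerance = 1e-12)
  expect_equal(by_tun$dw, ref$dw_mean, tolerance = 1e-12)

  # large-sample moments within 2%
  big <- generate_cohort(cohort_spec(n_sb = 10000, n_db = 10000, seed = 2))
  tr <- attr(big, "truth")
  sbf <- tr[tr$tunnel == "femur", ]
  expect_lt(abs(mean(sbf$d0) - 8.3) / 8.3, 0.02)
  expect_lt(abs(sd(sbf$d0) - 0.6) / 0.6, 0.02)

  # Year-0 truncation essentially never triggers at the default drill
  # sizes: worst case is the narrowest drill (5.8 +/- 0.4 vs the 4 mm floor)
  expect_lt(pnorm(4, 5.8, 0.4), 1e-3)
  expect_true(all(tr$d0 > 4))
  # widening truncation is part of the model: no draw falls below -0.5
  expect_true(all(tr$dw >= -0.5))

  expect_error(cohort_spec(n_sb = 1), "at least 2")
})

test_that("cohort generation is reproducible for a fixed seed", {
  c1 <- generate_cohort(cohort_spec(seed = 42))
  c2 <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("enrollment arithmetic reproduces the analyzed sample", {
  e <- enrollment_summary()
  expect_equal(e$invited - e$excluded_logistics - e$excluded_radiation -
                 e$excluded_lost - e$excluded_technical, 42)
  expect_equal(e$analyzed, 42)
  expect_equal(e$n_db + e$n_sb, e$analyzed)
})
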