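test_that("exact cylinder data are recovered to machine precision", {
  ax <- c(0.3, -0.2, 0.93)
  pts <- cylinder_surface_points(4, 30, n = 2000, axis_dir = ax, seed = 1)
  fit <- fit_cylinder(pts)
  expect_equal(fit$radius, 4, tolerance = 1e-6)
  expect_lt(acos(min(abs(sum(fit$axis_dir * ax / sqrt(sum(ax^2)))), 1)), 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  # oracle equivalence: closed-form radius with the KNOWN axis
  oracle <- acltunnel:::known_axis_radius(pts, c(0, 0, 0), ax)
  expect_equal(fit$radius, oracle, tolerance = 1e-9)
})

test_that("noisy cylinder radii are unbiased to 0.01 mm across seeds", {
  errs <- vapply(1:100, function(s) {
    pts <- cylinder_surface_points(4, 30, n = 2000, noise_sd = 0.1, seed = s)
    abs(fit_cylinder(pts)$radius - 4)
  }, numeric(1))
  expect_lt(max(errs), 0.01)
})

test_that("degenerate point clouds are rejected", {
  # points on a sphere
  withr::with_seed(1, {
    u <- matrix(rnorm(3 * 500), 500, 3)
    u <- 5 * u / sqrt(rowSums(u^2))
  })
  sph <- tibble::new_tibble(tibble::tibble(x = u[, 1], y = u[, 2], z = u[, 3]),
                            class = "tunnel_points")
  expect_error(fit_cylinder(sph), "degenerate|coplanar")

  # coplanar points
  withr::with_seed(2, {
    flat <- tibble::tibble(x = runif(200), y = runif(200), z = 0)
  })
  expect_error(fit_cylinder(tibble::new_tibble(flat, class = "tunnel_points")),
               "coplanar")

  expect_error(fit_cylinder(cylinder_surface_points(4, 30, n = 20)),
               "at least 50")
})

test_that("cylinder fits are invariant under rigid motions", {
  pts <- cylinder_surface_points(3.2, 25, n = 1500, seed = 3)
  f0 <- fit_cylinder(pts)
  withr::with_seed(11, {
    for (i in 1:5) {
      R <- acltunnel:::rotation_matrix(rnorm(3), runif(1, 0, pi))
      tr <- rnorm(3, 0, 20)
      pm <- sweep(cbind(pts$x, pts$y, pts$z) %*% t(R), 2, -tr)
      moved <- tibble::new_tibble(
        tibble::tibble(x = pm[, 1], y = pm[, 2], z = pm[, 3]),
        class = "tunnel_points")
      f <- fit_cylinder(moved)
      expect_equal(f$radius, f0$radius, tolerance = 1e-6)
      expect_equal(f$length, f0$length, tolerance = 1e-6)
    }
  })
})

test_that("scaling the cloud by s scales radius, diameter and sqrt(csa/pi) by s", {
  pts <- cylinder_surface_points(4, 30, n = 1500, seed = 4)
  f1 <- fit_cylinder(pts)
  for (s in c(0.5, 2.5)) {
    scaled <- tibble::new_tibble(
      tibble::tibble(x = s * pts$x, y = s * pts$y, z = s * pts$z),
      class = "tunnel_points")
    f <- fit_cylinder(scaled)
    expect_equal(f$radius, s * f1$radius, tolerance = 1e-6)
    expect_equal(f$diameter, s * f1$diameter, tolerance = 1e-6)
    expect_equal(sqrt(f$csa / pi), s * sqrt(f1$csa / pi), tolerance = 1e-6)
  }
})

test_that("csa and diameter are consistent for every fit", {
  ph <- perp_phantom(diameter = 7.2, length = 26)
  m <- measure_tunnel(mask_to_points(ph$masks[[1]]), jp_default())
  for (f in list(m$cylinder, m$aperture, m$at10mm)) {
    expect_equal(f$csa, pi * (f$diameter / 2)^2, tolerance = 1e-9)
  }
})

test_that("circle fits recover exact and conical cross-sections", {
  pts <- cylinder_surface_points(4, 30, n = 3000, seed = 6)
  cyl <- fit_cylinder(pts)
  jp0 <- joint_plane(c(0, 0, 0), c(0, 0, 1))
  for (pos in c(5, 15, 25)) {
    circ <- fit_circle_at(pts, cyl, pos, joint_plane = jp0)
    expect_equal(circ$radius, 4, tolerance = 1e-6)
  }
  # cone: radius 5.05 at the aperture tapering 0.01 mm/mm -> 4.95 at 10 mm
  cone <- cone_surface_points(5.05, 0.01, 30)
  ccyl <- fit_cylinder(cone)
  circ10 <- fit_circle_at(cone, ccyl, 10, joint_plane = jp0)
  expect_equal(circ10$radius, 4.95, tolerance = 0.02)
  circ0 <- fit_circle_at(cone, ccyl, 0.5, joint_plane = jp0)
  expect_gt(circ0$radius, circ10$radius)

  expect_error(fit_circle_at(pts, cyl, 60, joint_plane = jp0), "slab")
})

test_that("measure_tunnel reproduces a uniform phantom at the study's femoral drill size", {
  ph <- perp_phantom(diameter = 8.3, length = 30)
  m <- measure_tunnel(mask_to_points(ph$masks[[1]]), jp_default())
  expect_equal(m$cylinder$diameter, 8.3, tolerance = 0.3)
  expect_equal(m$aperture$diameter, 8.3, tolerance = 0.3)
  expect_equal(m$at10mm$diameter, 8.3, tolerance = 0.3)
  # aperture and 10-mm planes are perpendicular to the cylinder axis
  expect_equal(m$aperture$plane_normal, m$cylinder$axis_dir)
  expect_equal(m$at10mm$plane_normal, m$cylinder$axis_dir)
})

test_that("aperture-weighted widening yields aperture > 10-mm diameters", {
  t1 <- widen_tunnel(perp_tunnel(diameter = 8.4), 1.7, "aperture_weighted")
  ph <- generate_phantom(phantom_spec(), list(t1), seed = 1)
  m <- measure_tunnel(mask_to_points(ph$masks[[1]]), jp_default())
  expect_gt(m$aperture$diameter, m$at10mm$diameter)
  expect_equal(m$aperture$diameter, 10.1, tolerance = 0.3)
  expect_equal(m$at10mm$diameter, 9.25, tolerance = 0.3)
})

test_that("measurements are invariant under rigid rotation of the whole phantom", {
  ph <- perp_phantom(diameter = 8, length = 28)
  pts <- mask_to_points(ph$masks[[1]])
  jp <- jp_default()
  m0 <- glance(measure_tunnel(pts, jp))
  withr::with_seed(21, {
    R <- acltunnel:::rotation_matrix(rnorm(3), runif(1, 0.2, 1.2))
    tr <- rnorm(3, 0, 10)
  })
  pm <- sweep(cbind(pts$x, pts$y, pts$z) %*% t(R), 2, -tr)
  nm <- cbind(pts$nx, pts$ny, pts$nz) %*% t(R)
  rot <- tibble::new_tibble(
    tibble::tibble(x = pm[, 1], y = pm[, 2], z = pm[, 3],
                   nx = nm[, 1], ny = nm[, 2], nz = nm[, 3]),
    class = "tunnel_points")
  attr(rot, "spacing") <- attr(pts, "spacing")
  jp_rot <- joint_plane(drop(R %*% jp$point) + tr, drop(R %*% jp$normal))
  m1 <- glance(measure_tunnel(rot, jp_rot))
  for (col in c("diameter_cylinder", "diameter_aperture", "diameter_at10")) {
    expect_lt(abs(m1[[col]] - m0[[col]]), 0.05)
  }
})

test_that("communication detection matches constructed converging pairs", {
  jp <- jp_default()
  pair <- generate_communicating_pair(5, phantom_spec())
  cr <- detect_communication(pair$mask_a, pair$mask_b, jp)
  expect_true(cr$communicating)
  expect_lt(abs(cr$ridge_distance - 5), 1.5)

  sep <- generate_communicating_pair(NULL, phantom_spec())
  cr0 <- detect_communication(sep$mask_a, sep$mask_b, jp)
  expect_false(cr0$communicating)
  expect_true(all(cr0$gap_profile$gap[!is.na(cr0$gap_profile$gap)] > 0))

  # grid mismatch is rejected
  other <- perp_phantom(diameter = 6, length = 20)
  small <- tunnel_mask(pair$mask_a$voxels[1:48, , ], pair$mask_a$spacing)
  expect_error(detect_communication(small, pair$mask_b, jp), "same voxel grid")
})

test_that("masks below the joint plane are rejected", {
  ph <- perp_phantom()
  # a plane far above the whole phantom puts both masks at negative depth
  jp_high <- joint_plane(c(0, 0, 100), c(0, 0, 1))
  expect_error(detect_communication(ph$masks[[1]], ph$masks[[1]], jp_high),
               "opposite sides|below")
})
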