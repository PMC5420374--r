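#' Measure a tunnel: best-fit cylinder plus aperture and 10-mm circles
#'
#' The full measurement pipeline for one tunnel point set:
#'
#' 1. a preliminary axis from the first principal component of the points;
#' 2. end trimming ([trim_tunnel()]) with a margin that removes voxelised
#'    end caps (`r * tan(theta) +` half a voxel diagonal at each end,
#'    where `theta` is the axis-to-joint-normal angle);
#' 3. robust screw filtering ([filter_screw_outliers()]);
#' 4. the best-fit cylinder ([fit_cylinder()]), axis pointing into bone;
#' 5. best-fit circles at the aperture (axial coordinate 0, where the
#'    fitted axis crosses the joint plane) and at `at_depth` (10.0 mm),
#'    fitted on the untrimmed points so the aperture slab is populated —
#'    the circle fitter's robust trimming handles cap points.
#'
#' @param points A `tunnel_points` tibble from [mask_to_points()].
#' @param joint_plane A [joint_plane()].
#' @param slab_halfwidth Circle-fit slab half-width, mm (default 1.0).
#' @param at_depth Depth of the second circle, mm (default 10.0).
#' @param filter_screws Run the robust screw filter (default TRUE).
#' @param k_mad Robust threshold for the screw filter.
#' @param trim_range Optional explicit axial `c(a, b)` window, mm; by
#'   default computed from the data as described above.
#' @return A `tunnel_measurement`: `cylinder` ([fit_cylinder()] result),
#'   `aperture` and `at10mm` ([fit_circle_at()] results), labels, and the
#'   number of screw-filtered points. `tidy()` returns the six diameters
#'   and cross-sectional areas as one row.
#' @export
measure_tunnel <- function(points, joint_plane, slab_halfwidth = 1.0,
                           at_depth = 10, filter_screws = TRUE, k_mad = 3.5,
                           trim_range = NULL) {
  stopifnot(inherits(joint_plane, "joint_plane"))
  pm <- points_matrix(points)
  ctr <- colMeans(pm)
  dir0 <- unit(svd(sweep(pm, 2, ctr), nu = 0)$v[, 1])
  if (sum(dir0 * joint_plane$normal) < 0) dir0 <- -dir0

  sp <- attr(points, "spacing") %||% c(0.5, 0.5, 1.5)
  half_diag <- sqrt(sum(sp^2)) / 2
  origin0 <- line_plane_intersection(ctr, dir0, joint_plane)
  a0 <- axial_coord(pm, origin0, dir0)
  r_hat <- median(line_distance(pm, origin0, dir0))
  cos_t <- abs(sum(dir0 * joint_plane$normal))
  tan_t <- sqrt(max(1 - cos_t^2, 0)) / max(cos_t, 1e-6)
  margin <- r_hat * tan_t + half_diag
  if (is.null(trim_range)) {
    trim_range <- c(min(a0) + margin, max(a0) - margin)
  }
  trimmed <- trim_tunnel(points, dir0, trim_range, joint_plane)
  n_removed <- 0
  if (filter_screws) {
    trimmed <- filter_screw_outliers(trimmed, k_mad = k_mad)
    n_removed <- attr(trimmed, "n_removed")
  }
  cyl <- fit_cylinder(trimmed, joint_plane = joint_plane)
  aperture <- fit_circle_at(points, cyl, 0, slab_halfwidth,
                            joint_plane = joint_plane)
  at10 <- fit_circle_at(points, cyl, at_depth, slab_halfwidth,
                        joint_plane = joint_plane)
  m <- structure(list(
    cylinder = cyl, aperture = aperture, at10mm = at10,
    side = attr(points, "side"), bundle = attr(points, "bundle"),
    n_screw_points_removed = n_removed, at_depth = at_depth
  ), class = "tunnel_measurement")
  validate_measurement(m)
  m
}

validate_measurement <- function(m, window = c(2, 20)) {
  ds <- c(m$cylinder$diameter, m$aperture$diameter, m$at10mm$diameter)
  if (any(ds < window[1]) || any(ds > window[2])) {
    warn(sprintf("measured diameters (%s mm) fall outside the sanity window [%g, %g] mm",
                 paste(sprintf("%.1f", ds), collapse = ", "),
                 window[1], window[2]))
  }
  invisible(m)
}

#' @export
print.tunnel_measurement <- function(x, ...) {
  cat(sprintf("<tunnel_measurement> %s/%s\n",
              x$side %||% "?", x$bundle %||% "?"))
  cat(sprintf("  cylinder: %.2f mm (%.1f mm^2)\n", x$cylinder$diameter, x$cylinder$csa))
  cat(sprintf("  aperture: %.2f mm (%.1f mm^2)\n", x$aperture$diameter, x$aperture$csa))
  cat(sprintf("  at %g mm: %.2f mm (%.1f mm^2)\n", x$at_depth, x$at10mm$diameter, x$at10mm$csa))
  invisible(x)
}

#' @export
tidy.tunnel_measurement <- function(x, ...) {
  tibble(
    side = x$side %||% NA_character_, bundle = x$bundle %||% NA_character_,
    level = c("cylinder", "aperture", "10mm"),
    diameter_mm = c(x$cylinder$diameter, x$aperture$diameter, x$at10mm$diameter),
    csa_mm2 = c(x$cylinder$csa, x$aperture$csa, x$at10mm$csa),
    rms_residual = c(x$cylinder$rms_residual, x$aperture$rms_residual,
                     x$at10mm$rms_residual)
  )
}

#' @export
glance.tunnel_measurement <- function(x, ...) {
  tibble(
    diameter_cylinder = x$cylinder$diameter,
    diameter_aperture = x$aperture$diameter,
    diameter_at10 = x$at10mm$diameter,
    csa_cylinder = x$cylinder$csa,
    csa_aperture = x$aperture$csa,
    csa_at10 = x$at10mm$csa,
    n_screw_points_removed = x$n_screw_points_removed
  )
}

#' Measure every tunnel of a phantom
#'
#' Convenience wrapper: extracts surface points from each mask of a
#' [generate_phantom()] result and runs [measure_tunnel()].
#'
#' @param phantom A `tunnel_phantom`.
#' @param method Surface extraction method for [mask_to_points()].
#' @param ... Passed to [measure_tunnel()].
#' @return A tibble with one row per tunnel and level, joined with the
#'   phantom ground truth.
#' @export
measure_phantom <- function(phantom, method = "voxel_faces", ...) {
  stopifnot(inherits(phantom, "tunnel_phantom"))
  jp <- phantom$spec$joint_plane
  purrr::map2_dfr(phantom$masks, phantom$truth$tunnel, function(mask, id) {
    pts <- mask_to_points(mask, method = method)
    m <- measure_tunnel(pts, jp, ...)
    dplyr::mutate(tidy(m), tunnel = id, .before = 1)
  })
}
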