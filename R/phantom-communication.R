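#' Generate a converging (possibly communicating) tunnel pair
#'
#' Builds two tunnels that share a joint-line aperture region and diverge
#' with depth, as in a double-bundle reconstruction whose AM and PL tunnels
#' communicate. The entry separation and divergence half-angle are solved
#' so the tunnel surfaces touch for depths shallower than
#' `ridge_distance_mm` and are separated by cortical bone beyond it.
#' `ridge_distance_mm = NULL` produces fully separated tunnels.
#'
#' @param ridge_distance_mm Depth (mm, from the joint line) at which the
#'   separating cortical ridge begins, or `NULL` for no communication.
#' @param spec A [phantom_spec()].
#' @param diameters Length-2 tunnel diameters, mm (AM, PL).
#' @param length Tunnel length, mm; must exceed `ridge_distance_mm + 5`.
#' @param max_half_angle Maximum divergence half-angle (radians).
#' @param seed Intensity-noise seed.
#' @return List with `mask_a`, `mask_b`, `truth` (tibble with
#'   `communicating` and `ridge_distance`), and the full `phantom`.
#' @export
generate_communicating_pair <- function(ridge_distance_mm = 5,
                                        spec = phantom_spec(),
                                        diameters = c(7.1, 5.8),
                                        length = 25,
                                        max_half_angle = 30 * pi / 180,
                                        seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), length(diameters) == 2)
  r1 <- diameters[1] / 2
  r2 <- diameters[2] / 2
  jp <- spec$joint_plane
  b <- perp_basis(jp$normal)
  center <- jp$point +
    b$e1 * (spec$grid_shape[1] - 1) * spec$spacing[1] / 2 +
    b$e2 * (spec$grid_shape[2] - 1) * spec$spacing[2] / 2
  ## keep the pair centred on the grid regardless of where jp$point sits
  center <- project_to_plane(grid_center(spec), jp)

  communicating <- !is.null(ridge_distance_mm)
  if (communicating) {
    R <- ridge_distance_mm
    stop_if_not_scalar_number(R, "ridge_distance_mm")
    if (R <= 0) abort("`ridge_distance_mm` must be positive")
    if (R >= length - 5) {
      abort("requested ridge distance too deep for the tunnel length")
    }
    ## entry separation s and half-angle a with s + 2 R tan(a) = r1 + r2
    s <- max(0.8, (r1 + r2) - 2 * R * tan(max_half_angle))
    half_angle <- atan(((r1 + r2) - s) / (2 * R))
    if (half_angle <= 0.01) {
      abort("geometry cannot achieve the requested ridge at these radii")
    }
  } else {
    s <- r1 + r2 + 3
    half_angle <- 10 * pi / 180
  }

  d1 <- unit(cos(half_angle) * jp$normal - sin(half_angle) * b$e1)
  d2 <- unit(cos(half_angle) * jp$normal + sin(half_angle) * b$e1)
  t1 <- tunnel_spec(center - (s / 2) * b$e1, d1, diameter = diameters[1],
                    length = length, side = "femur", bundle = "AM")
  t2 <- tunnel_spec(center + (s / 2) * b$e1, d2, diameter = diameters[2],
                    length = length, side = "femur", bundle = "PL")
  ph <- generate_phantom(spec, list(t1, t2), seed = seed,
                         expect_overlap = communicating)
  truth <- tibble(
    communicating = communicating,
    ridge_distance = if (communicating) ridge_distance_mm else NA_real_,
    entry_separation = s,
    half_angle_deg = half_angle * 180 / pi
  )
  list(mask_a = ph$masks[[1]], mask_b = ph$masks[[2]],
       truth = truth, phantom = ph)
}

grid_center <- function(spec) {
  (spec$grid_shape - 1) * spec$spacing / 2
}

project_to_plane <- function(p, plane) {
  p - sum((p - plane$point) * plane$normal) * plane$normal
}
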