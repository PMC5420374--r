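#' Define the joint-line plane
#'
#' The joint line is modelled as a plane in world millimetre coordinates.
#' Its normal points from the joint space *into* the bone, so positive
#' signed distances are "inside bone" and the tunnel's axial coordinate
#' increases away from the joint.
#'
#' @param point Numeric length-3, a point on the plane (mm).
#' @param normal Numeric length-3, plane normal; normalised internally and
#'   oriented as given (pointing into bone).
#' @return An object of class `joint_plane`.
#' @examples
#' joint_plane(c(0, 0, 10), c(0, 0, 1))
#' @export
joint_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3)
  structure(list(point = as.numeric(point), normal = unit(as.numeric(normal))),
            class = "joint_plane")
}

#' @export
print.joint_plane <- function(x, ...) {
  cat("<joint_plane> point:", paste(signif(x$point, 4), collapse = ", "),
      " normal:", paste(signif(x$normal, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Specify a CT-like phantom grid
#'
#' Describes the voxel grid, spacing, joint plane and intensity model of a
#' synthetic knee phantom. The default grid (96 x 96 x 40 voxels at
#' 0.4 x 0.4 x 1.5 mm) keeps the anisotropy of a clinical knee CT
#' (1.5 mm slice thickness, fine in-plane resolution) at desk scale; a full
#' 512 x 512 in-plane grid is available by changing `grid_shape`.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param spacing Numeric length-3 mm per voxel (in-plane, in-plane, slice).
#' @param joint_plane A [joint_plane()]; default: slice plane at z = 6 mm
#'   with bone above.
#' @param bone_intensity,background_intensity HU-like scalars for bone and
#'   for the tunnel void / joint space.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 40),
                         spacing = c(0.4, 0.4, 1.5),
                         joint_plane = NULL,
                         bone_intensity = 1200,
                         background_intensity = 50,
                         noise_sd = 20) {
  stopifnot(length(grid_shape) == 3, length(spacing) == 3)
  if (any(spacing <= 0)) abort("`spacing` must be strictly positive on all axes")
  if (any(grid_shape < 2)) abort("`grid_shape` must be at least 2 per axis")
  if (is.null(joint_plane)) {
    joint_plane <- joint_plane(c(0, 0, 6), c(0, 0, 1))
  }
  stopifnot(inherits(joint_plane, "joint_plane"))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 joint_plane = joint_plane,
                 bone_intensity = bone_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Specify one drilled tunnel
#'
#' A tunnel is a (generalised) cylinder: an entry point on the joint plane,
#' a unit axis pointing into bone, a radius profile as a function of axial
#' depth, and a length. Freshly drilled (Year-0) tunnels have a constant
#' radius; widened tunnels get their profile from [widen_tunnel()].
#'
#' Drill sizes respect the hamstring-graft minima used clinically: at least
#' 5.0 mm diameter for a PL bundle and 6.0 mm for an AM bundle.
#'
#' @param entry_point Numeric length-3 mm coordinates of the aperture centre
#'   (should lie on the joint plane).
#' @param axis_direction Numeric length-3, direction into bone (normalised).
#' @param diameter Drill diameter in mm (used when `radius_profile` is NULL).
#' @param radius_profile Optional vectorised function depth_mm -> radius_mm.
#' @param length Tunnel length along the axis, mm.
#' @param side `"femur"` or `"tibia"`.
#' @param bundle `"SB"`, `"AM"` or `"PL"`.
#' @return A `tunnel_spec` object.
#' @examples
#' tunnel_spec(c(0, 0, 6), c(0, 0, 1), diameter = 8, length = 30)
#' @export
tunnel_spec <- function(entry_point, axis_direction, diameter = NULL,
                        radius_profile = NULL, length = 30,
                        side = c("femur", "tibia"), bundle = c("SB", "AM", "PL")) {
  side <- match.arg(side)
  bundle <- match.arg(bundle)
  stopifnot(length(entry_point) == 3, length(axis_direction) == 3)
  stop_if_not_scalar_number(length, "length")
  if (length <= 0) abort("tunnel `length` must be positive")
  if (is.null(radius_profile)) {
    if (is.null(diameter)) abort("give either `diameter` or `radius_profile`")
    stop_if_not_scalar_number(diameter, "diameter")
    if (diameter <= 0) abort("`diameter` must be positive")
    if (bundle == "PL" && diameter < 5.0) {
      abort("PL-bundle drill diameter must be at least 5.0 mm")
    }
    if (bundle == "AM" && diameter < 6.0) {
      abort("AM-bundle drill diameter must be at least 6.0 mm")
    }
    r <- diameter / 2
    radius_profile <- function(a) rep_len(r, base::length(a))
  }
  dir <- unit(as.numeric(axis_direction))
  tn <- structure(list(entry_point = as.numeric(entry_point),
                       axis_direction = dir,
                       radius_profile = radius_profile,
                       length = length,
                       side = side, bundle = bundle),
                  class = "tunnel_spec")
  rr <- tn$radius_profile(seq(0, length, length.out = 201))
  if (any(rr <= 0)) abort("radius_profile must be positive over [0, length]")
  tn
}

## radius profile evaluated at standard depths + length average
tunnel_truth_diameters <- function(tn, at_depth = 10) {
  a <- seq(0, tn$length, length.out = 401)
  r <- tn$radius_profile(a)
  tibble(
    diameter_aperture = 2 * tn$radius_profile(0),
    diameter_at10 = 2 * tn$radius_profile(min(at_depth, tn$length)),
    diameter_cylinder = 2 * mean(r)
  )
}

#' @export
print.tunnel_spec <- function(x, ...) {
  cat(sprintf("<tunnel_spec> %s/%s, length %.1f mm, aperture diameter %.2f mm\n",
              x$side, x$bundle, x$length, 2 * x$radius_profile(0)))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d voxels at %.2f x %.2f x %.2f mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
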