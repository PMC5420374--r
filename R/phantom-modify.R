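#' Widen a tunnel between timepoints
#'
#' Applies a diameter increase `delta_mm` to a tunnel's radius profile.
#' `"uniform"` widens the whole tunnel equally. `"aperture_weighted"`
#' reflects the windshield-wiper pattern reported for real tunnels (more
#' widening at the aperture than deeper in bone): the full `delta_mm / 2`
#' radius increase is applied at depth 0, decaying linearly to
#' `delta_mm / 4` at `decay_depth` (10 mm by default) and constant beyond.
#'
#' @param tn A [tunnel_spec()].
#' @param delta_mm Diameter change in mm (may be mildly negative; the
#'   resulting radius must stay positive).
#' @param profile `"uniform"` or `"aperture_weighted"`.
#' @param decay_depth Depth (mm) over which the aperture-weighted increase
#'   decays; the deep-tunnel fraction of the aperture increase is
#'   `floor_frac`.
#' @param floor_frac Fraction of the aperture radius increase retained
#'   beyond `decay_depth` (default 0.5).
#' @return A new `tunnel_spec` with the widened radius profile.
#' @examples
#' t0 <- tunnel_spec(c(0, 0, 6), c(0, 0, 1), diameter = 8.4, length = 30)
#' t1 <- widen_tunnel(t0, 1.7, "aperture_weighted")
#' 2 * t1$radius_profile(c(0, 10))   # 10.1 at the aperture, 9.25 at 10 mm
#' @export
widen_tunnel <- function(tn, delta_mm, profile = c("uniform", "aperture_weighted"),
                         decay_depth = 10, floor_frac = 0.5) {
  stopifnot(inherits(tn, "tunnel_spec"))
  profile <- match.arg(profile)
  stop_if_not_scalar_number(delta_mm, "delta_mm")
  old <- tn$radius_profile
  wfun <- if (profile == "uniform") {
    function(a) rep_len(1, length(a))
  } else {
    function(a) 1 - (1 - floor_frac) * pmin(pmax(a, 0), decay_depth) / decay_depth
  }
  new_profile <- function(a) old(a) + (delta_mm / 2) * wfun(a)
  rmin <- min(new_profile(seq(0, tn$length, length.out = 401)))
  if (rmin <= 0) {
    abort(sprintf("widening delta %.2f mm would make the radius non-positive (min %.3f mm)",
                  delta_mm, rmin))
  }
  out <- tn
  out$radius_profile <- new_profile
  out
}

#' Add an interference-screw tip artifact to a tunnel mask
#'
#' Models a tibial interference screw whose tip protrudes diagonally out of
#' the tunnel wall near the distal end: a sphere of `tip_radius`, centred
#' `tip_offset` away from the distal axis point, is unioned onto the mask.
#' The lobe must protrude from the wall while staying attached to it.
#'
#' @param mask A [tunnel_mask()] (by convention a tibial tunnel).
#' @param tip_offset Numeric length-3 mm offset of the sphere centre from
#'   the distal end of the tunnel axis.
#' @param tip_radius Sphere radius in mm; 0 leaves the mask unchanged.
#' @param joint_plane Optional [joint_plane()] used to orient "distal"
#'   (the end farthest into bone); otherwise the positive end of the
#'   principal axis is used.
#' @return The augmented `tunnel_mask`.
#' @export
add_screw_artifact <- function(mask, tip_offset, tip_radius, joint_plane = NULL) {
  stopifnot(inherits(mask, "tunnel_mask"), length(tip_offset) == 3)
  stop_if_not_scalar_number(tip_radius, "tip_radius")
  if (tip_radius < 0) abort("`tip_radius` must be non-negative")
  if (tip_radius == 0) return(mask)
  ctr <- mask_voxel_centers(mask)
  pc <- prcomp(ctr, center = TRUE, scale. = FALSE)
  dir <- unit(pc$rotation[, 1])
  if (!is.null(joint_plane) && sum(dir * joint_plane$normal) < 0) dir <- -dir
  a <- axial_coord(ctr, colMeans(ctr), dir)
  distal_pt <- colMeans(ctr) + max(a) * dir
  tip_center <- distal_pt + as.numeric(tip_offset)

  d <- dim(mask$voxels)
  world_hi <- mask$origin + (d - 1) * mask$spacing
  if (any(tip_center < mask$origin) || any(tip_center > world_hi)) {
    abort("screw tip centre lies outside the grid")
  }
  xi <- mask$origin[1] + (seq_len(d[1]) - 1) * mask$spacing[1]
  yi <- mask$origin[2] + (seq_len(d[2]) - 1) * mask$spacing[2]
  zi <- mask$origin[3] + (seq_len(d[3]) - 1) * mask$spacing[3]
  dx2 <- (xi - tip_center[1])^2
  dy2 <- (yi - tip_center[2])^2
  dz2 <- (zi - tip_center[3])^2
  sphere <- array(outer(outer(dx2, dy2, "+"), dz2, "+") <= tip_radius^2, d)
  if (!any(sphere & !mask$voxels)) return(mask)  # lobe fully inside: no-op
  new_vox <- mask$voxels | sphere
  if (!is_connected(new_vox)) {
    abort("screw lobe is disconnected from the tunnel; it must protrude from the wall")
  }
  out <- mask
  out$voxels <- new_vox
  out
}

#' Perturb a segmentation like an imperfect rater
#'
#' Emulates manual slice-by-slice segmentation editing: within each axial
#' slice the in-plane tunnel boundary is moved outward by `rater_bias_mm`
#' on average, with independent Gaussian jitter of `boundary_noise_sd_mm`
#' per boundary decision. Implemented as a per-slice signed-distance
#' re-threshold, so a pure bias of +b mm dilates the boundary by b.
#' Deterministic for a given seed.
#'
#' @param mask A [tunnel_mask()].
#' @param rater_bias_mm Mean outward boundary shift (mm); negative erodes.
#' @param boundary_noise_sd_mm Voxel-wise Gaussian jitter SD (mm).
#' @param seed Integer seed.
#' @return The perturbed `tunnel_mask`.
#' @export
perturb_segmentation <- function(mask, rater_bias_mm = 0,
                                 boundary_noise_sd_mm = 0, seed = 1) {
  stopifnot(inherits(mask, "tunnel_mask"))
  if (rater_bias_mm == 0 && boundary_noise_sd_mm == 0) return(mask)
  d <- dim(mask$voxels)
  sp <- mask$spacing
  reach_mm <- abs(rater_bias_mm) + 4 * boundary_noise_sd_mm
  band_steps <- ceiling(reach_mm / min(sp[1:2])) + 1L
  new_vox <- mask$voxels

  with_seed(seed, {
    for (k in seq_len(d[3])) {
      sl <- mask$voxels[, , k]
      if (!any(sl)) next
      edges <- slice_boundary_points(sl, sp[1:2])
      if (nrow(edges) == 0) next
      band <- slice_band(sl, band_steps)
      cand <- which(band, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      cx <- (cand[, 1] - 1) * sp[1]
      cy <- (cand[, 2] - 1) * sp[2]
      ## unsigned distance from each candidate centre to the boundary
      dd <- sqrt(outer(cx, edges[, 1], "-")^2 + outer(cy, edges[, 2], "-")^2)
      dmin <- apply(dd, 1, min)
      inside <- sl[cand]
      sdist <- ifelse(inside, -dmin, dmin)
      eps <- rnorm(length(sdist), 0, boundary_noise_sd_mm)
      keep <- sdist <= rater_bias_mm + eps
      sl2 <- sl
      sl2[cand] <- keep
      new_vox[, , k] <- sl2
    }
  })
  if (!any(new_vox)) abort("perturbation removed the whole mask")
  if (!is_connected(new_vox)) {
    abort("perturbation destroyed mask connectivity; reduce bias/noise")
  }
  out <- mask
  out$voxels <- new_vox
  out
}

## in-plane boundary sample points of a 2D slice: midpoints of in/out
## voxel-centre pairs (4-neighbourhood), in slice mm coordinates
slice_boundary_points <- function(sl, sp2) {
  d <- dim(sl)
  pts <- list()
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (s in shifts) {
    shifted <- matrix(FALSE, d[1], d[2])
    i1 <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
    j1 <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
    shifted[i1, j1] <- sl[i1 - s[1], j1 - s[2]]
    edge <- sl & !shifted
    idx <- which(edge, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ## edge = in-voxel whose neighbour at -s is out; the surface sample
      ## sits half a voxel toward that neighbour
      pts[[length(pts) + 1]] <- cbind((idx[, 1] - 1 - s[1] / 2) * sp2[1],
                                      (idx[, 2] - 1 - s[2] / 2) * sp2[2])
    }
  }
  if (length(pts) == 0) return(matrix(0, 0, 2))
  do.call(rbind, pts)
}

## voxels within `steps` 8-connected dilations of the slice boundary
slice_band <- function(sl, steps) {
  grown <- sl
  for (i in seq_len(steps)) {
    d <- dim(grown)
    g <- grown
    g[-1, ] <- g[-1, ] | grown[-d[1], ]
    g[-d[1], ] <- g[-d[1], ] | grown[-1, ]
    g[, -1] <- g[, -1] | grown[, -d[2]]
    g[, -d[2]] <- g[, -d[2]] | grown[, -1]
    g[-1, -1] <- g[-1, -1] | grown[-d[1], -d[2]]
    g[-d[1], -d[2]] <- g[-d[1], -d[2]] | grown[-1, -1]
    g[-1, -d[2]] <- g[-1, -d[2]] | grown[-d[1], -1]
    g[-d[1], -1] <- g[-d[1], -1] | grown[-1, -d[2]]
    grown <- g
  }
  shrunk <- sl
  for (i in seq_len(steps)) {
    d <- dim(shrunk)
    g <- shrunk
    g[-1, ] <- g[-1, ] & shrunk[-d[1], ]
    g[-d[1], ] <- g[-d[1], ] & shrunk[-1, ]
    g[, -1] <- g[, -1] & shrunk[, -d[2]]
    g[, -d[2]] <- g[, -d[2]] & shrunk[, -1]
    shrunk <- g
  }
  grown & !shrunk
}
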