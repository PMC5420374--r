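#' Threshold-based seeded tunnel segmentation
#'
#' The reproducible counterpart of an interactive threshold tool: selects
#' voxels with intensity in `[lo, hi]`, keeps the 26-connected component
#' containing `seed_point`, and fills in-plane holes slice by slice (as a
#' rater would when painting each axial slice).
#'
#' @param vol An [image_volume()].
#' @param lo,hi Intensity window (inclusive); `lo < hi`.
#' @param seed_point World mm coordinates of a point inside the tunnel.
#' @param joint_plane Optional [joint_plane()]; when given, the selection
#'   is restricted to the bone side, separating the tunnel void from the
#'   contiguous joint space (the role of the rater's manual cut at the
#'   aperture).
#' @param side,bundle Labels for the resulting mask.
#' @return A [tunnel_mask()]. If the selected component touches the grid
#'   boundary (seed placed in background/joint space rather than in a
#'   tunnel) it is returned with a warning so the caller can reject it.
#' @export
threshold_segment <- function(vol, lo, hi, seed_point, joint_plane = NULL,
                              side = c("femur", "tibia"),
                              bundle = c("SB", "AM", "PL")) {
  stopifnot(inherits(vol, "image_volume"))
  if (!(lo < hi)) abort("threshold window must have lo < hi")
  d <- dim(vol$voxels)
  idx <- round((as.numeric(seed_point) - vol$origin) / vol$spacing) + 1
  if (any(idx < 1) || any(idx > d)) abort("seed point lies outside the grid")
  sel <- vol$voxels >= lo & vol$voxels <= hi
  if (!is.null(joint_plane)) {
    xi <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
    yi <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
    zi <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
    n <- joint_plane$normal
    p0 <- joint_plane$point
    sdist <- outer(outer((xi - p0[1]) * n[1], (yi - p0[2]) * n[2], "+"),
                   (zi - p0[3]) * n[3], "+")
    sel <- sel & array(sdist >= 0, d)
  }
  if (!sel[idx[1], idx[2], idx[3]]) {
    abort(sprintf("empty selection: seed intensity %.1f is outside the window [%g, %g]",
                  vol$voxels[idx[1], idx[2], idx[3]], lo, hi))
  }
  comp <- connected_component(sel, idx)
  if (!any(comp)) abort(sprintf("empty selection in threshold window [%g, %g]", lo, hi))
  comp <- fill_holes_slicewise(comp)
  if (touches_boundary(comp)) {
    warn("segmented component touches the grid boundary; the seed may not be inside a tunnel")
  }
  tunnel_mask(comp, vol$spacing, vol$origin,
              side = match.arg(side), bundle = match.arg(bundle))
}

## fill 2D holes in each axial slice: background connected to the slice
## border is outside; everything else becomes mask
fill_holes_slicewise <- function(vox) {
  d <- dim(vox)
  for (k in seq_len(d[3])) {
    sl <- vox[, , k]
    if (!any(sl)) next
    outside <- matrix(FALSE, d[1], d[2])
    border <- !sl
    outside[1, ] <- border[1, ]
    outside[d[1], ] <- border[d[1], ]
    outside[, 1] <- border[, 1]
    outside[, d[2]] <- border[, d[2]]
    repeat {
      g <- outside
      g[-1, ] <- g[-1, ] | outside[-d[1], ]
      g[-d[1], ] <- g[-d[1], ] | outside[-1, ]
      g[, -1] <- g[, -1] | outside[, -d[2]]
      g[, -d[2]] <- g[, -d[2]] | outside[, -1]
      g <- g & !sl
      if (sum(g) == sum(outside)) break
      outside <- g
    }
    vox[, , k] <- !outside
  }
  vox
}

touches_boundary <- function(vox) {
  d <- dim(vox)
  any(vox[1, , ]) || any(vox[d[1], , ]) ||
    any(vox[, 1, ]) || any(vox[, d[2], ]) ||
    any(vox[, , 1]) || any(vox[, , d[3]])
}

#' Dice overlap between two masks
#'
#' @param a,b [tunnel_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "tunnel_mask"), inherits(b, "tunnel_mask"),
            all(dim(a$voxels) == dim(b$voxels)))
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}
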