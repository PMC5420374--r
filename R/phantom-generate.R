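#' Generate a ground-truthed CT-like knee phantom
#'
#' Builds a bone block on an anisotropic voxel grid, drills the requested
#' tunnels into it, and returns the intensity volume, one binary mask per
#' tunnel, and an analytic ground-truth table. A voxel belongs to a tunnel
#' when its centre lies within the tunnel's radius profile of the axis, at
#' axial depth within `[0, length]`, and on the bone side of the joint
#' plane. Intensities are `background_intensity` inside tunnels (and in the
#' joint space), `bone_intensity` elsewhere in bone, plus Gaussian noise.
#'
#' Geometry is deterministic: the seed only affects intensity noise, never
#' the masks or the ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param tunnels A list of [tunnel_spec()] objects.
#' @param seed Integer seed for the intensity noise.
#' @param expect_overlap Set `TRUE` for deliberately communicating tunnel
#'   pairs to suppress the overlap warning.
#' @return A `tunnel_phantom`: list with `volume` ([image_volume()]),
#'   `masks` (list of [tunnel_mask()]), `truth` (tibble, one row per
#'   tunnel), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 24)),
#'                        list(tunnel_spec(c(9.4, 9.4, 6), c(0, 0, 1),
#'                                         diameter = 8, length = 24)),
#'                        seed = 1)
#' ph$truth
#' @export
generate_phantom <- function(spec, tunnels, seed = 1, expect_overlap = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (inherits(tunnels, "tunnel_spec")) tunnels <- list(tunnels)
  d <- spec$grid_shape
  sp <- spec$spacing
  ## voxel-centre world coordinates, one long column per axis
  xi <- (seq_len(d[1]) - 1) * sp[1]
  yi <- (seq_len(d[2]) - 1) * sp[2]
  zi <- (seq_len(d[3]) - 1) * sp[3]
  X <- rep(xi, times = d[2] * d[3])
  Y <- rep(rep(yi, each = d[1]), times = d[3])
  Z <- rep(zi, each = d[1] * d[2])
  P <- cbind(X, Y, Z)
  world_lo <- c(0, 0, 0)
  world_hi <- (d - 1) * sp

  side_bone <- drop(sweep(P, 2, spec$joint_plane$point) %*% spec$joint_plane$normal) >= 0

  masks <- vector("list", length(tunnels))
  truth <- vector("list", length(tunnels))
  any_tunnel <- rep(FALSE, nrow(P))
  for (ti in seq_along(tunnels)) {
    tn <- tunnels[[ti]]
    check_tunnel_in_grid(tn, spec, world_lo, world_hi)
    dx <- sweep(P, 2, tn$entry_point)
    a <- drop(dx %*% tn$axis_direction)
    rad2 <- pmax(rowSums(dx^2) - a^2, 0)
    ## the bore is truncated by the joint plane (bone surface) at the
    ## mouth, not by a = 0: an oblique drill removes the uphill wedge of
    ## bone-side material at slightly negative axial coordinates too
    inside <- side_bone & a <= tn$length &
      rad2 <= tn$radius_profile(pmin(pmax(a, 0), tn$length))^2
    if (!any(inside)) abort("tunnel produced an empty mask; check the spec")
    vox <- array(inside, d)
    masks[[ti]] <- tunnel_mask(vox, sp, origin = c(0, 0, 0),
                               side = tn$side, bundle = tn$bundle)
    td <- tunnel_truth_diameters(tn)
    truth[[ti]] <- tibble(
      tunnel = paste0(tn$side, "_", tn$bundle, "_", ti),
      side = tn$side, bundle = tn$bundle,
      diameter_aperture = td$diameter_aperture,
      diameter_at10 = td$diameter_at10,
      diameter_cylinder = td$diameter_cylinder,
      length = tn$length,
      axis_x = tn$axis_direction[1], axis_y = tn$axis_direction[2],
      axis_z = tn$axis_direction[3],
      entry_x = tn$entry_point[1], entry_y = tn$entry_point[2],
      entry_z = tn$entry_point[3]
    )
    if (any(any_tunnel & inside) && !expect_overlap) {
      warn("tunnel masks overlap but were not flagged as a communicating pair")
    }
    any_tunnel <- any_tunnel | inside
  }

  intens <- ifelse(side_bone & !any_tunnel, spec$bone_intensity,
                   spec$background_intensity)
  noise <- with_seed(seed, rnorm(length(intens), 0, spec$noise_sd))
  vol <- image_volume(array(intens + noise, d), sp, origin = c(0, 0, 0))

  structure(list(volume = vol, masks = masks,
                 truth = dplyr::bind_rows(truth), spec = spec),
            class = "tunnel_phantom")
}

## the tunnel (restricted to the bone side) must fit inside the grid
check_tunnel_in_grid <- function(tn, spec, world_lo, world_hi) {
  a <- seq(0, tn$length, length.out = 41)
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  b <- perp_basis(tn$axis_direction)
  ctr <- outer(a, tn$axis_direction) + matrix(tn$entry_point, length(a), 3, byrow = TRUE)
  r <- tn$radius_profile(a)
  pts <- do.call(rbind, lapply(seq_along(ang), function(i) {
    ctr + r * matrix(cos(ang[i]) * b$e1 + sin(ang[i]) * b$e2,
                     length(a), 3, byrow = TRUE)
  }))
  on_bone <- drop(sweep(pts, 2, spec$joint_plane$point) %*% spec$joint_plane$normal) >= 0
  pts <- pts[on_bone, , drop = FALSE]
  margin <- spec$spacing / 2
  ok <- sweep(pts, 2, world_lo + margin, ">=") & sweep(pts, 2, world_hi - margin, "<=")
  if (!all(ok)) {
    abort(sprintf("tunnel %s/%s exits the phantom grid; enlarge the grid or move the entry point",
                  tn$side, tn$bundle))
  }
  invisible(TRUE)
}

#' @export
print.tunnel_phantom <- function(x, ...) {
  cat(sprintf("<tunnel_phantom> %d tunnel(s) on %s grid\n",
              length(x$masks),
              paste(x$spec$grid_shape, collapse = " x ")))
  print(x$truth[, c("tunnel", "diameter_aperture", "diameter_at10",
                    "diameter_cylinder")])
  invisible(x)
}
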