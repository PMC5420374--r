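#' Extract boundary points from a tunnel mask
#'
#' Converts a binary tunnel mask into a surface point set in world mm
#' coordinates, ready for primitive fitting.
#'
#' * `"voxel_faces"`: centres of exposed voxel faces (faces between a mask
#'   voxel and a background voxel), with the outward face normal recorded.
#' * `"isosurface"`: 0.5-level crossings of a box-smoothed (3x3x3 mean)
#'   binary field, linearly interpolated along grid edges — a smoothed
#'   isosurface vertex sampling that reduces voxelisation staircase noise.
#'
#' @param mask A [tunnel_mask()].
#' @param method Surface extraction method.
#' @return A `tunnel_points` tibble with columns `x`, `y`, `z` (and face
#'   normals `nx`, `ny`, `nz` for `"voxel_faces"`); voxel spacing and
#'   provenance are kept as attributes.
#' @export
mask_to_points <- function(mask, method = c("voxel_faces", "isosurface")) {
  stopifnot(inherits(mask, "tunnel_mask"))
  method <- match.arg(method)
  if (sum(mask$voxels) < 2) abort("mask too small: no fittable surface")
  pts <- if (method == "voxel_faces") {
    face_center_points(mask)
  } else {
    isosurface_points(mask)
  }
  if (nrow(pts) == 0) abort("mask produced no surface points")
  out <- tibble::new_tibble(pts, class = "tunnel_points")
  attr(out, "spacing") <- mask$spacing
  attr(out, "provenance") <- method
  attr(out, "side") <- mask$side
  attr(out, "bundle") <- mask$bundle
  out
}

face_center_points <- function(mask) {
  d <- dim(mask$voxels)
  sp <- mask$spacing
  res <- list()
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(dirs))) {
    dir <- dirs[r, ]
    axis <- which(dir != 0)
    step <- dir[axis]
    ## neighbour in direction `dir` is background (or out of grid)
    nb <- shift_mask(mask$voxels, axis, -step)
    ## voxels at the grid edge in that direction are exposed too
    edge <- array(FALSE, d)
    if (step == 1) {
      pos <- lapply(d, seq_len); pos[[axis]] <- d[axis]
    } else {
      pos <- lapply(d, seq_len); pos[[axis]] <- 1L
    }
    edge[pos[[1]], pos[[2]], pos[[3]]] <- TRUE
    exposed <- mask$voxels & (!nb | edge)
    idx <- which(exposed, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ctr <- sweep((idx - 1) %*% diag(sp), 2, -mask$origin) +
      matrix(dir * sp / 2, nrow(idx), 3, byrow = TRUE)
    res[[length(res) + 1]] <- tibble(
      x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
      nx = dir[1], ny = dir[2], nz = dir[3]
    )
  }
  dplyr::bind_rows(res)
}

isosurface_points <- function(mask) {
  f <- box_smooth3(mask$voxels * 1.0)
  d <- dim(f)
  sp <- mask$spacing
  org <- mask$origin
  pts <- list()
  for (axis in 1:3) {
    a <- f
    b <- shift_num(f, axis, 1)           # value of next voxel along axis
    valid <- array(TRUE, d)
    pos <- lapply(d, seq_len); pos[[axis]] <- d[axis]
    valid[pos[[1]], pos[[2]], pos[[3]]] <- FALSE
    cross <- valid & ((a - 0.5) * (b - 0.5) < 0)
    idx <- which(cross, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    t <- (0.5 - f[cross]) / (b[cross] - f[cross])
    ctr <- sweep((idx - 1) %*% diag(sp), 2, -org)
    ctr[, axis] <- ctr[, axis] + t * sp[axis]
    ## outward normal ~ -grad(f) (f is 1 inside), central differences in mm
    g <- vapply(1:3, function(ax) {
      ((shift_num(f, ax, 1) - shift_num(f, ax, -1)) / (2 * sp[ax]))[cross]
    }, numeric(sum(cross)))
    g <- matrix(g, ncol = 3)
    gn <- sqrt(rowSums(g^2))
    gn[gn < 1e-12] <- 1
    pts[[length(pts) + 1]] <- tibble(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                                     nx = -g[, 1] / gn, ny = -g[, 2] / gn,
                                     nz = -g[, 3] / gn)
  }
  dplyr::bind_rows(pts)
}

## 3x3x3 box mean with zero padding
box_smooth3 <- function(a) {
  out <- array(0, dim(a))
  cnt <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    s <- a
    if (dx != 0) s <- shift_num(s, 1, dx)
    if (dy != 0) s <- shift_num(s, 2, dy)
    if (dz != 0) s <- shift_num(s, 3, dz)
    out <- out + s
    cnt <- cnt + 1
  }
  out / cnt
}

shift_num <- function(a, axis, step) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- lapply(d, seq_len)
  if (step == 1) {
    dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis]
  } else {
    dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

points_matrix <- function(points) {
  cbind(points$x, points$y, points$z)
}

#' Trim a tunnel point set along its axis
#'
#' Keeps points whose signed axial coordinate — 0 where the axis crosses
#' the joint plane, increasing into bone — lies in `keep_range`. Used to
#' isolate the graft-bearing part of the tunnel and drop the suspension
#' device track and voxelised end caps before cylinder fitting.
#'
#' @param points A `tunnel_points` tibble from [mask_to_points()].
#' @param axis_hint Unit vector of a preliminary axis estimate (e.g. the
#'   first principal component of the points).
#' @param keep_range `c(a, b)` axial window in mm, `a < b`.
#' @param joint_plane A [joint_plane()] defining axial coordinate 0.
#' @param min_points Minimum points that must survive (default 50).
#' @return The trimmed `tunnel_points` tibble.
#' @export
trim_tunnel <- function(points, axis_hint, keep_range, joint_plane,
                        min_points = 50) {
  stopifnot(length(keep_range) == 2)
  if (!(keep_range[1] < keep_range[2])) {
    abort("`keep_range` must satisfy a < b")
  }
  axis_hint <- unit(as.numeric(axis_hint))
  if (sum(axis_hint * joint_plane$normal) < 0) axis_hint <- -axis_hint
  pm <- points_matrix(points)
  origin <- line_plane_intersection(colMeans(pm), axis_hint, joint_plane)
  a <- axial_coord(pm, origin, axis_hint)
  keep <- a >= keep_range[1] & a <= keep_range[2]
  if (sum(keep) < min_points) {
    abort(sprintf("only %d points survive trimming to [%g, %g]; need %d",
                  sum(keep), keep_range[1], keep_range[2], min_points))
  }
  out <- points[keep, ]
  attributes(out)[c("spacing", "provenance", "side", "bundle")] <-
    attributes(points)[c("spacing", "provenance", "side", "bundle")]
  out
}

#' Robustly filter screw-tip outliers from a tunnel point set
#'
#' Reproducible surrogate for manually filtering the protruding tip of a
#' tibial interference screw: iteratively fit a cylinder, compute radial
#' residuals, drop points more than `k_mad` robust standard deviations
#' (MAD) above the median residual, and refit until convergence or
#' `max_iter`. Only outward outliers are removed, so a clean cylinder is
#' left untouched.
#'
#' @param points A `tunnel_points` tibble.
#' @param max_iter Maximum fit-drop-refit cycles (default 5).
#' @param k_mad Outlier threshold in MAD units (default 3.5);
#'   `Inf` disables filtering.
#' @return The filtered `tunnel_points` with attributes `n_removed` and
#'   `iterations`.
#' @export
filter_screw_outliers <- function(points, max_iter = 5, k_mad = 3.5) {
  n0 <- nrow(points)
  keep <- rep(TRUE, n0)
  iters <- 0
  for (i in seq_len(max_iter)) {
    iters <- i
    cur <- points[keep, ]
    fit <- fit_cylinder(cur)
    res <- line_distance(points_matrix(cur), fit$axis_point, fit$axis_dir) - fit$radius
    md <- median(res)
    s <- mad(res)
    if (!is.finite(k_mad)) break
    thr <- md + k_mad * max(s, 1e-12)
    drop_now <- res > thr
    if (!any(drop_now)) break
    keep[which(keep)][drop_now] <- FALSE
    if (sum(!keep) > 0.4 * n0) {
      abort(sprintf("screw filter removed %d of %d points (> 40%%); mask is likely not a tunnel",
                    sum(!keep), n0))
    }
  }
  out <- points[keep, ]
  attributes(out)[c("spacing", "provenance", "side", "bundle")] <-
    attributes(points)[c("spacing", "provenance", "side", "bundle")]
  attr(out, "n_removed") <- n0 - nrow(out)
  attr(out, "iterations") <- iters
  out
}
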