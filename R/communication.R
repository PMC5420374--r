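#' Detect communication between two tunnels
#'
#' Two tunnels communicate when the separating cortical bone ridge is
#' missing at the level of the joint line. The joint-normal depth range
#' `[0, max_depth]` is divided into bins one slice thick; within each bin
#' the minimum bone gap between the two masks is computed as the smallest
#' voxel-centre distance minus the voxel extent projected along the
#' connecting direction, so face- or corner-adjacent (or overlapping)
#' voxels give gap <= 0, i.e. contact. The tunnels communicate if the bin
#' at the joint line is in contact; the ridge distance is the depth at
#' which the gap profile first becomes (and stays) positive, located by
#' linear interpolation between bin centres.
#'
#' @param mask_a,mask_b [tunnel_mask()] objects on the same grid and the
#'   same side of the joint plane.
#' @param joint_plane A [joint_plane()].
#' @param max_depth Depth range to profile, mm (default 20).
#' @param bin_width Depth bin, mm; defaults to the slice thickness
#'   (third spacing component).
#' @return A `communication_result`: `communicating`, `ridge_distance`
#'   (mm from the joint line to the first separating bone, `NA` when not
#'   communicating or never separating), and `gap_profile` (tibble of
#'   depth bin centre vs minimum bone gap).
#' @export
detect_communication <- function(mask_a, mask_b, joint_plane,
                                 max_depth = 20, bin_width = NULL) {
  stopifnot(inherits(mask_a, "tunnel_mask"), inherits(mask_b, "tunnel_mask"))
  if (!all(dim(mask_a$voxels) == dim(mask_b$voxels)) ||
      !isTRUE(all.equal(mask_a$spacing, mask_b$spacing)) ||
      !isTRUE(all.equal(mask_a$origin, mask_b$origin))) {
    abort("masks must share the same voxel grid")
  }
  bin_width <- bin_width %||% mask_a$spacing[3]
  pa <- mask_voxel_centers(mask_a)
  pb <- mask_voxel_centers(mask_b)
  da <- drop(sweep(pa, 2, joint_plane$point) %*% joint_plane$normal)
  db <- drop(sweep(pb, 2, joint_plane$point) %*% joint_plane$normal)
  if (median(da) < 0 || median(db) < 0) {
    abort("masks lie on opposite sides of (or below) the joint plane")
  }

  edges <- seq(0, max_depth, by = bin_width)
  centers <- edges + bin_width / 2
  gap <- gap_depth <- rep(NA_real_, length(centers))
  for (i in seq_along(centers)) {
    lo <- edges[i]; hi <- edges[i] + bin_width
    ia <- da >= lo & da < hi
    ib <- db >= lo & db < hi
    if (!any(ia) || !any(ib)) next
    A <- pa[ia, , drop = FALSE]
    B <- pb[ib, , drop = FALSE]
    g <- min_bone_gap(A, B, mask_a$spacing, da[ia], db[ib])
    gap[i] <- g$gap
    gap_depth[i] <- g$depth
  }
  valid <- which(!is.na(gap))
  if (length(valid) == 0) abort("tunnels have no voxels in the depth range")
  communicating <- isTRUE(gap[valid[1]] <= 0) && centers[valid[1]] <= bin_width

  ridge <- NA_real_
  if (communicating) {
    ## first index after which the gap stays positive
    pos <- !is.na(gap) & gap > 0
    idx <- NA_integer_
    for (i in seq_along(gap)) {
      tail_ok <- pos[i:length(gap)] | is.na(gap[i:length(gap)])
      if (!is.na(gap[i]) && gap[i] > 0 && all(tail_ok)) { idx <- i; break }
    }
    if (!is.na(idx) && idx > 1) {
      ## interpolate the zero crossing using the depths of the minimising
      ## voxel pairs (gap varies within a bin; the pair depth locates it)
      i0 <- max(valid[valid < idx])   # last contact bin
      g0 <- gap[i0]; g1 <- gap[idx]
      d0 <- gap_depth[i0]; d1 <- gap_depth[idx]
      ridge <- if (d1 > d0) d0 + (0 - g0) / (g1 - g0) * (d1 - d0) else edges[idx]
      ridge <- max(ridge, 0)
    } else if (!is.na(idx)) {
      ridge <- edges[idx]
    }
  }
  structure(list(
    communicating = communicating, ridge_distance = ridge,
    gap_profile = tibble(depth = centers, gap = gap, pair_depth = gap_depth)
  ), class = "communication_result")
}

## minimum direction-corrected bone gap between two voxel-centre sets:
## for each pair, centre distance minus the voxel extent projected on the
## connecting direction (sum_k |d_k| * spacing_k / |d|); chunked for
## memory; also reports the mean depth of the minimising pair
min_bone_gap <- function(A, B, spacing, depth_a, depth_b, chunk = 2000L) {
  best <- Inf
  best_depth <- NA_real_
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ac <- A[s:e, , drop = FALSE]
    dx <- abs(outer(Ac[, 1], B[, 1], "-"))
    dy <- abs(outer(Ac[, 2], B[, 2], "-"))
    dz <- abs(outer(Ac[, 3], B[, 3], "-"))
    d <- sqrt(dx^2 + dy^2 + dz^2)
    proj <- dx * spacing[1] + dy * spacing[2] + dz * spacing[3]
    g <- d - proj / pmax(d, 1e-12)
    g[d < 1e-12] <- -max(spacing)
    m <- min(g)
    if (m < best) {
      best <- m
      w <- which(g == m, arr.ind = TRUE)[1, ]
      best_depth <- (depth_a[s:e][w[1]] + depth_b[w[2]]) / 2
    }
  }
  list(gap = best, depth = best_depth)
}

#' @export
print.communication_result <- function(x, ...) {
  if (x$communicating) {
    cat(sprintf("<communication_result> communicating; ridge at %.1f mm from the joint line\n",
                x$ridge_distance))
  } else {
    cat("<communication_result> not communicating (separating ridge present at the joint line)\n")
  }
  invisible(x)
}

#' @export
tidy.communication_result <- function(x, ...) {
  tibble(communicating = x$communicating, ridge_distance = x$ridge_distance)
}

#' @rdname detect_communication
#' @param x A `communication_result`.
#' @param ... Ignored.
#' @export
autoplot.communication_result <- function(x, ...) {
  df <- dplyr::filter(x$gap_profile, !is.na(.data$gap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$gap)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "depth from joint line (mm)", y = "minimum bone gap (mm)",
                  title = if (x$communicating) {
                    sprintf("Communicating; ridge at %.1f mm", x$ridge_distance)
                  } else "Not communicating") +
    ggplot2::theme_minimal()
}
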