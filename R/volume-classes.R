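#' 3D image volume and tunnel mask containers
#'
#' `image_volume()` wraps a 3D scalar array with anisotropic voxel spacing
#' and a world-space origin; `tunnel_mask()` wraps a binary array aligned to
#' the same grid, labelled with the bone side and graft bundle. Voxel
#' (i, j, k) (1-based) has world centre `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3D numeric array (volume) or logical/0-1 array (mask).
#' @param spacing Numeric length-3, mm per axis; strictly positive.
#' @param origin Numeric length-3, world coordinates of voxel (1,1,1)'s
#'   centre, mm.
#' @param side,bundle Tunnel labels (mask only).
#' @return An `image_volume` / `tunnel_mask` object.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array")
  if (any(dim(voxels) < 2)) abort("volume must have at least 2 voxels per axis")
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive values (mm)")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
tunnel_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                        side = c("femur", "tibia"), bundle = c("SB", "AM", "PL")) {
  side <- match.arg(side)
  bundle <- match.arg(bundle)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array")
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive values (mm)")
  }
  storage.mode(voxels) <- "logical"
  if (!any(voxels)) abort("tunnel mask is empty")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), side = side, bundle = bundle),
            class = "tunnel_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' @export
print.tunnel_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tunnel_mask> %s/%s, %d voxels set on %d x %d x %d grid\n",
              x$side, x$bundle, sum(x$voxels), d[1], d[2], d[3]))
  invisible(x)
}

## world coordinates (n x 3) of the mask's TRUE voxel centres
mask_voxel_centers <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  sweep((idx - 1) %*% diag(mask$spacing), 2, -mask$origin)
}

## shift a 3D logical array by one voxel along axis (+1/-1), padding FALSE
shift_mask <- function(a, axis, step) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (step == 1) {
    dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1)
  } else {
    dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## 26-connected (or 6-connected) one-voxel binary dilation
dilate_mask <- function(a, connectivity = 26) {
  out <- a
  steps <- if (connectivity == 6) {
    list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))
  } else {
    NULL
  }
  if (!is.null(steps)) {
    for (s in steps) out <- out | shift_mask(a, s[1], s[2])
    return(out)
  }
  ## 26-connectivity: compose axis dilations (gives the full 3x3x3 box)
  for (axis in 1:3) {
    out <- out | shift_mask(out, axis, 1) | shift_mask(out, axis, -1)
  }
  out
}

## connected component of `seed_idx` (length-3 index) within logical array,
## grown by iterative dilation; connectivity 26 by default
connected_component <- function(a, seed_idx, connectivity = 26) {
  if (!a[seed_idx[1], seed_idx[2], seed_idx[3]]) {
    return(array(FALSE, dim(a)))
  }
  comp <- array(FALSE, dim(a))
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  repeat {
    grown <- dilate_mask(comp, connectivity) & a
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

## TRUE if the mask forms one 26-connected component
is_connected <- function(voxels) {
  idx <- which(voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  comp <- connected_component(voxels, idx[1, ])
  sum(comp) == sum(voxels)
}
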