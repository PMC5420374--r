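## Small vector-geometry helpers. All geometry is done in world
## millimetre coordinates; voxel index (i, j, k) maps to world space as
## origin + (index - 1) * spacing, i.e. coordinates of voxel CENTRES.

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

## deterministic orthonormal basis {e1, e2} spanning the plane
## perpendicular to unit vector d
perp_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(pracma_cross(ref, d))
  e2 <- pracma_cross(d, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## rotation matrix about a unit axis by angle (Rodrigues)
rotation_matrix <- function(axis, angle) {
  axis <- unit(axis)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## signed distance of points (n x 3 matrix) from a plane
plane_distance <- function(pts, plane) {
  sweep(pts, 2, plane$point) %*% plane$normal |> drop()
}

## distance of points from the infinite line through `point` along unit `dir`
line_distance <- function(pts, point, dir) {
  d <- sweep(pts, 2, point)
  a <- d %*% dir
  sqrt(pmax(rowSums(d^2) - drop(a)^2, 0))
}

## axial coordinate of points along `dir` with origin at `point`
axial_coord <- function(pts, point, dir) {
  drop(sweep(pts, 2, point) %*% dir)
}

## intersection of the line (point, dir) with a plane; errors if parallel
line_plane_intersection <- function(point, dir, plane) {
  denom <- sum(dir * plane$normal)
  if (abs(denom) < 1e-9) abort("axis is parallel to the joint plane")
  t <- sum((plane$point - point) * plane$normal) / denom
  point + t * dir
}

## run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
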