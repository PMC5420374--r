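#' Best-fit circle in a cross-sectional slab
#'
#' Measures the tunnel cross-section at a given depth: points whose axial
#' coordinate (along the best-fit cylinder axis, 0 at the joint-line
#' intersection) lies within `slab_halfwidth` of `axial_position` are
#' projected onto the plane through that position perpendicular to the
#' cylinder axis, and a circle is fitted in 2D.
#'
#' The fit is robust to non-rim points (voxelised aperture caps, screw
#' remnants): starting from the cylinder prior (centre on the axis, radius
#' of the cylinder), points with two-sided radial residuals beyond
#' `k_mad` MADs are trimmed over a few iterations; the surviving rim is
#' then fitted algebraically (Kasa) and refined by geometric Gauss-Newton.
#'
#' @param points A `tunnel_points` tibble.
#' @param cyl A [fit_cylinder()] result defining the axis.
#' @param axial_position Depth along the axis, mm (0 = aperture).
#' @param slab_halfwidth Half-width of the slab, mm (default 1.0,
#'   about one slice thickness).
#' @param joint_plane [joint_plane()] defining axial coordinate 0; when
#'   `NULL`, coordinate 0 is at the cylinder's `axis_point`.
#' @param k_mad Robust trimming threshold (MAD units).
#' @param min_points Minimum rim points (default 8).
#' @return A `circle_fit`: `center` (3D mm), `plane_normal`, `radius`,
#'   `diameter`, `csa`, `slab_halfwidth`, `n_points`, `rms_residual`.
#' @export
fit_circle_at <- function(points, cyl, axial_position, slab_halfwidth = 1.0,
                          joint_plane = NULL, k_mad = 3.5, min_points = 8) {
  stopifnot(inherits(cyl, "cylinder_fit"))
  pm <- points_matrix(points)
  origin <- if (is.null(joint_plane)) {
    cyl$axis_point
  } else {
    line_plane_intersection(cyl$axis_point, cyl$axis_dir, joint_plane)
  }
  a <- axial_coord(pm, origin, cyl$axis_dir)
  in_slab <- abs(a - axial_position) <= slab_halfwidth
  if (sum(in_slab) < min_points) {
    abort(sprintf("only %d points in the slab at %.1f mm (halfwidth %.1f mm); need %d",
                  sum(in_slab), axial_position, slab_halfwidth, min_points))
  }
  ## voxelised tunnel ends expose cap faces whose centres lie across the
  ## whole cross-section, not on the rim: drop surface points whose
  ## outward normal points against the axis (toward the joint space)
  if (all(c("nx", "ny", "nz") %in% names(points))) {
    nrm <- cbind(points$nx, points$ny, points$nz)[in_slab, , drop = FALSE]
    along <- drop(nrm %*% cyl$axis_dir)
    cap <- !is.na(along) & along < -0.3
    if (sum(!cap) >= min_points) in_slab[which(in_slab)[cap]] <- FALSE
  }
  b <- perp_basis(cyl$axis_dir)
  plane_origin <- origin + axial_position * cyl$axis_dir
  rel <- sweep(pm[in_slab, , drop = FALSE], 2, plane_origin)
  u <- drop(rel %*% b$e1)
  v <- drop(rel %*% b$e2)

  ## robust trimming anchored at the cylinder prior (centre 0,0, radius r),
  ## then re-anchored at successive circle fits
  cx <- 0; cy <- 0; r <- cyl$radius
  keep <- rep(TRUE, length(u))
  for (i in 1:4) {
    d <- sqrt((u - cx)^2 + (v - cy)^2)
    res <- d - r
    s <- mad(res[keep], center = 0)
    if (!is.finite(s) || s < 1e-9) break
    new_keep <- abs(res) <= k_mad * s
    if (sum(new_keep) < min_points) break
    if (all(new_keep == keep)) break
    keep <- new_keep
    kf <- kasa_circle(u[keep], v[keep])
    ref <- circle_gauss_newton(u[keep], v[keep], kf)
    cx <- ref[1]; cy <- ref[2]; r <- ref[3]
  }
  uu <- u[keep]; vv <- v[keep]
  if (length(uu) < min_points) {
    abort(sprintf("fewer than %d rim points after trimming in the slab at %.1f mm",
                  min_points, axial_position))
  }
  init <- kasa_circle(uu, vv)
  ref <- circle_gauss_newton(uu, vv, init)
  if (ref[3] <= 0) abort("circle fit produced a non-positive radius")
  center3 <- plane_origin + ref[1] * b$e1 + ref[2] * b$e2
  resid <- sqrt((uu - ref[1])^2 + (vv - ref[2])^2) - ref[3]
  structure(list(
    center = center3, plane_normal = cyl$axis_dir,
    radius = ref[3], diameter = 2 * ref[3], csa = pi * ref[3]^2,
    slab_halfwidth = slab_halfwidth, axial_position = axial_position,
    n_points = length(uu), rms_residual = sqrt(mean(resid^2))
  ), class = "circle_fit")
}

## Kasa algebraic circle fit: linear least squares on
## x^2 + y^2 = 2 a x + 2 b y + c
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  sol <- tryCatch(solve(crossprod(A), crossprod(A, z)),
                  error = function(e) abort("degenerate slab: collinear points in circle fit"))
  a <- sol[1]; b <- sol[2]
  r2 <- sol[3] + a^2 + b^2
  if (r2 <= 0) abort("degenerate slab: algebraic circle fit failed")
  c(a, b, sqrt(r2))
}

## geometric refinement: Gauss-Newton on (cx, cy, r)
circle_gauss_newton <- function(x, y, par, max_iter = 50, tol = 1e-12) {
  for (i in seq_len(max_iter)) {
    dx <- x - par[1]; dy <- y - par[2]
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-12] <- 1e-12
    r <- d - par[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    par <- par - drop(step)
    if (max(abs(step)) < tol) break
  }
  par
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> at %.1f mm: diameter %.3f mm, CSA %.2f mm^2 (%d rim points)\n",
              x$axial_position, x$diameter, x$csa, x$n_points))
  invisible(x)
}

#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(
    primitive = "circle", axial_position = x$axial_position,
    diameter = x$diameter, radius = x$radius, csa = x$csa,
    rms_residual = x$rms_residual, n_points = x$n_points
  )
}
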