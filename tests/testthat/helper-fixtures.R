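# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

jp_default <- function() joint_plane(c(0, 0, 6), c(0, 0, 1))

# a perpendicular drilled tunnel centred on the default phantom grid
perp_tunnel <- function(diameter = 8, length = 30, side = "femur",
                        bundle = "SB") {
  tunnel_spec(c(19, 19, 6), c(0, 0, 1), diameter = diameter, length = length,
              side = side, bundle = bundle)
}

perp_phantom <- function(diameter = 8, length = 30, noise_sd = 20, seed = 1,
                         side = "femur", bundle = "SB") {
  generate_phantom(phantom_spec(noise_sd = noise_sd),
                   list(perp_tunnel(diameter, length, side, bundle)),
                   seed = seed)
}

# an oblique tunnel tilted `tilt_deg` from the slice normal, entry shifted
# so the bore stays inside the default grid
oblique_phantom <- function(diameter = 8, tilt_deg = 30, length = 26,
                            azimuth = 0, seed = 1) {
  t <- tilt_deg * pi / 180
  ax <- c(sin(t) * cos(azimuth), sin(t) * sin(azimuth), cos(t))
  entry <- c(19, 19, 6) - (length / 2) * c(ax[1], ax[2], 0)
  generate_phantom(phantom_spec(),
                   list(tunnel_spec(entry, ax, diameter = diameter,
                                    length = length)),
                   seed = seed)
}

# exact points on a cone: radius r0 - taper * a at axial depth a
cone_surface_points <- function(r0, taper, length, n = 3000, seed = 1) {
  withr::with_seed(seed, {
    a <- runif(n, 0, length)
    th <- runif(n, 0, 2 * pi)
    r <- r0 - taper * a
    tibble::new_tibble(
      tibble::tibble(x = r * cos(th), y = r * sin(th), z = a),
      class = "tunnel_points"
    )
  })
}

# variance-component rater matrix with known true ICC
vc_rater_matrix <- function(n = 200, k = 3, s_subj = 2, s_rater = 0.5,
                            s_err = sqrt(0.75), seed = 1) {
  withr::with_seed(seed, {
    outer(rnorm(n, 0, s_subj), rep(1, k)) +
      outer(rep(1, n), rnorm(k, 0, s_rater)) +
      matrix(rnorm(n * k, 0, s_err), n, k)
  })
}
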