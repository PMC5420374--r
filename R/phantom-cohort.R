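#' Default per-tunnel widening parameters
#'
#' Baseline (Year-0) diameter mean/SD and one-year widening mean/SD, in mm,
#' for each tunnel type of the two surgical techniques: single-bundle (SB,
#' one femoral and one tibial tunnel) and double-bundle (DB, anteromedial
#' AM and posterolateral PL tunnels in each bone). The values are
#' best-fit-cylinder summaries typical of hamstring-graft ACL
#' reconstructions measured with 3D CT immediately post-op and at 1 year.
#'
#' @return A tibble with columns `group`, `tunnel`, `side`, `bundle`,
#'   `d0_mean`, `d0_sd`, `dw_mean`, `dw_sd`.
#' @export
default_widening_params <- function() {
  tibble::tribble(
    ~group, ~tunnel,     ~side,   ~bundle, ~d0_mean, ~d0_sd, ~dw_mean, ~dw_sd,
    "SB",   "femur",     "femur", "SB",        8.3,    0.6,      1.4,    0.9,
    "SB",   "tibia",     "tibia", "SB",       10.0,    1.0,      1.0,    1.0,
    "DB",   "femur_AM",  "femur", "AM",        7.1,    0.7,      0.5,    0.6,
    "DB",   "femur_PL",  "femur", "PL",        5.8,    0.4,      0.8,    1.0,
    "DB",   "tibia_AM",  "tibia", "AM",        9.1,    0.8,      0.7,    0.8,
    "DB",   "tibia_PL",  "tibia", "PL",        7.0,    0.6,      0.5,    0.6
  )
}

#' Specify a paired two-timepoint cohort
#'
#' @param n_sb,n_db Subjects per technique group (defaults 22 SB, 20 DB —
#'   the analyzed sample of the emulated study design).
#' @param params Per-tunnel parameter tibble as in
#'   [default_widening_params()]; SDs must be non-negative.
#' @param widening_profile Spatial widening profile passed to
#'   [widen_tunnel()] in voxel mode; in fast mode `"uniform"` makes all
#'   three measurement levels carry the same widening.
#' @param tunnel_length Tunnel length in mm (fast-mode analytic levels and
#'   voxel-mode drilling).
#' @param d0_truncate Lower truncation for Year-0 diameters (mm, redrawn
#'   below); keeps phantoms physical given >= 5 mm drills.
#' @param dw_truncate Lower truncation for subject widening (mm).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_sb = 22, n_db = 20, params = default_widening_params(),
                        widening_profile = c("uniform", "aperture_weighted"),
                        tunnel_length = 30, d0_truncate = 4, dw_truncate = -0.5,
                        seed = 1) {
  widening_profile <- match.arg(widening_profile)
  if (n_sb < 2 || n_db < 2) abort("need at least 2 subjects per group")
  stopifnot(all(c("group", "tunnel", "d0_mean", "d0_sd", "dw_mean", "dw_sd")
                %in% names(params)))
  if (any(params$d0_sd < 0) || any(params$dw_sd < 0)) abort("SDs must be >= 0")
  structure(list(n_sb = as.integer(n_sb), n_db = as.integer(n_db),
                 params = params, widening_profile = widening_profile,
                 tunnel_length = tunnel_length, d0_truncate = d0_truncate,
                 dw_truncate = dw_truncate, seed = as.integer(seed)),
            class = "cohort_spec")
}

## truncated-normal draw by redrawing rejected values
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1
    if (guard > 1000) abort("truncated-normal rejection did not terminate")
  }
  x
}

#' Generate a paired Year-0 / Year-1 cohort
#'
#' Draws, per subject and tunnel type, a Year-0 diameter
#' `Normal(d0_mean, d0_sd)` truncated above `d0_truncate`, and a subject
#' widening `Normal(dw_mean, dw_sd)` truncated at `dw_truncate`, then
#' emits analytic measurements at the three levels (cylinder, aperture,
#' 10 mm). With the default `"uniform"` profile the drawn widening applies
#' equally at all levels; `"aperture_weighted"` scales it so the drawn
#' value is the cylinder (length-averaged) widening with aperture > 10 mm.
#'
#' @param cs A [cohort_spec()].
#' @return A `tunnel_cohort` tibble in long format (`subject`, `group`,
#'   `tunnel`, `level`, `timepoint`, `diameter_mm`, `csa_mm2`) with the
#'   per-subject truth table in `attr(, "truth")`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(coh, group, tunnel)
#' @export
generate_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  subjects <- tibble(
    subject = sprintf("S%03d", seq_len(cs$n_db + cs$n_sb)),
    group = c(rep("DB", cs$n_db), rep("SB", cs$n_sb))
  )
  draws <- with_seed(cs$seed, {
    grid <- dplyr::inner_join(subjects, cs$params, by = "group",
                              relationship = "many-to-many")
    grid$d0 <- rnorm_trunc(nrow(grid), grid$d0_mean, grid$d0_sd, cs$d0_truncate)
    grid$dw <- rnorm_trunc(nrow(grid), grid$dw_mean, grid$dw_sd, cs$dw_truncate)
    grid
  })

  ## per-level widening factors relative to the drawn (cylinder) widening
  lv <- widening_level_factors(cs$widening_profile, cs$tunnel_length)
  long <- draws |>
    dplyr::select("subject", "group", "tunnel", "d0", "dw") |>
    tidyr::crossing(tibble(level = c("cylinder", "aperture", "10mm"),
                           factor = c(lv["cylinder"], lv["aperture"], lv["10mm"]))) |>
    dplyr::mutate(year0 = .data$d0, year1 = .data$d0 + .data$dw * .data$factor) |>
    dplyr::select(-"d0", -"dw", -"factor") |>
    tidyr::pivot_longer(c("year0", "year1"), names_to = "timepoint",
                        values_to = "diameter_mm") |>
    dplyr::mutate(csa_mm2 = pi * (.data$diameter_mm / 2)^2) |>
    dplyr::arrange(.data$subject, .data$tunnel, .data$level, .data$timepoint)

  out <- tibble::new_tibble(long, class = "tunnel_cohort")
  attr(out, "truth") <- draws |>
    dplyr::select("subject", "group", "tunnel", "d0", "dw") |>
    dplyr::mutate(delta_pct = 100 * .data$dw / .data$d0)
  attr(out, "spec") <- cs
  out
}

## cylinder-normalised level factors: the drawn widening is the
## length-averaged (cylinder) one
widening_level_factors <- function(profile, length, decay_depth = 10,
                                   floor_frac = 0.5) {
  if (profile == "uniform") {
    return(c(cylinder = 1, aperture = 1, `10mm` = 1))
  }
  a <- seq(0, length, length.out = 401)
  w <- 1 - (1 - floor_frac) * pmin(a, decay_depth) / decay_depth
  wbar <- mean(w)
  c(cylinder = 1, aperture = 1 / wbar, `10mm` = floor_frac / wbar)
}

#' Study enrollment bookkeeping
#'
#' The prospective cohort design this package emulates: 56 patients
#' invited, minus 8 withdrawn for logistical reasons, 1 declining the
#' additional radiation, 2 lost to follow-up and 3 excluded for technical
#' CT errors, leaving 42 analyzed subjects (20 DB and 22 SB).
#'
#' @return A tibble with the enrollment arithmetic and the derived
#'   `analyzed`, `n_db`, `n_sb` counts.
#' @export
enrollment_summary <- function() {
  invited <- 56
  exclusions <- c(logistics = 8, declined_radiation = 1,
                  lost_followup = 2, technical_error = 3)
  tibble(
    invited = invited,
    excluded_logistics = exclusions[["logistics"]],
    excluded_radiation = exclusions[["declined_radiation"]],
    excluded_lost = exclusions[["lost_followup"]],
    excluded_technical = exclusions[["technical_error"]],
    analyzed = invited - sum(exclusions),
    n_db = 20L,
    n_sb = (invited - sum(exclusions)) - 20L
  )
}
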