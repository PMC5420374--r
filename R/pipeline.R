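#' Pipeline configuration
#'
#' A single declarative configuration drives the simulate -> measure ->
#' analyze pipeline. `run_config()` merges user values (a named list or a
#' YAML file) over the defaults, validates them, and attaches a stable
#' content hash that every downstream output embeds for provenance.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @return A validated `run_config` list with attribute `hash`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    output_dir = "acltunnel-run",
    seed = 1L,
    n_sb = 22L, n_db = 20L,
    widening_profile = "uniform",
    tunnel_length = 30,
    grid_shape = c(96L, 96L, 40L),
    spacing = c(0.4, 0.4, 1.5),
    joint_plane_point = c(0, 0, 6),
    joint_plane_normal = c(0, 0, 1),
    noise_sd = 20,
    n_voxel_subjects = 2L,
    slab_halfwidth = 1.0,
    at_depth = 10,
    k_mad = 3.5,
    max_iter = 5L,
    bootstrap_B = 2000L,
    n_raters = 3L,
    rater_sigma = 0.1,
    error_sigma = 0.6,
    alpha = 0.05
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (any(cfg$spacing <= 0)) abort("config `spacing` must be positive")
  if (cfg$slab_halfwidth <= 0) abort("config `slab_halfwidth` must be positive")
  if (cfg$n_sb < 2 || cfg$n_db < 2) abort("config group sizes must be >= 2")
  if (cfg$bootstrap_B < 200) abort("config `bootstrap_B` must be >= 200")
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_phantom_spec <- function(cfg) {
  phantom_spec(grid_shape = cfg$grid_shape, spacing = cfg$spacing,
               joint_plane = joint_plane(cfg$joint_plane_point,
                                         cfg$joint_plane_normal),
               noise_sd = cfg$noise_sd)
}

#' Simulate a study cohort to disk
#'
#' Generates the paired two-timepoint cohort (42 subjects by default:
#' 20 DB and 22 SB), writes the long-format measurement manifest and the
#' per-subject ground truth as CSV, and voxelises the first
#' `n_voxel_subjects` subjects per group as NIfTI label volumes with a
#' JSON ground-truth sidecar.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the cohort tibble and written paths.
#' @export
simulate_study <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- cohort_spec(n_sb = cfg$n_sb, n_db = cfg$n_db,
                    widening_profile = cfg$widening_profile,
                    tunnel_length = cfg$tunnel_length, seed = cfg$seed)
  cohort <- generate_cohort(cs)
  manifest_path <- file.path(cfg$output_dir, "cohort_measurements.csv")
  truth_path <- file.path(cfg$output_dir, "cohort_truth.csv")
  utils::write.csv(as.data.frame(cohort), manifest_path, row.names = FALSE)
  utils::write.csv(as.data.frame(attr(cohort, "truth")), truth_path,
                   row.names = FALSE)

  mask_files <- character(0)
  if (cfg$n_voxel_subjects > 0) {
    mask_files <- write_voxel_subjects(cohort, cfg)
  }
  meta <- list(config = unclass(cfg), config_hash = attr(cfg, "hash"),
               seed = cfg$seed, n_subjects = dplyr::n_distinct(cohort$subject))
  jsonlite::write_json(meta, file.path(cfg$output_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, manifest = manifest_path,
                 truth = truth_path, mask_files = mask_files,
                 config_hash = attr(cfg, "hash")))
}

## voxelise the first n subjects per group at both timepoints
write_voxel_subjects <- function(cohort, cfg) {
  spec <- config_phantom_spec(cfg)
  truth <- attr(cohort, "truth")
  pick <- truth |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_head(n = cfg$n_voxel_subjects) |>
    dplyr::ungroup()
  jp <- spec$joint_plane
  ctr <- project_to_plane(grid_center(spec), jp)
  files <- character(0)
  rows <- truth |> dplyr::semi_join(pick, by = c("subject", "group"))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    info <- strsplit(r$tunnel, "_")[[1]]
    side <- info[1]
    bundle <- if (length(info) > 1) info[2] else "SB"
    ## lateral offset per tunnel so DB pairs don't overlap
    off <- switch(bundle, SB = 0, AM = -6, PL = 6)
    t0 <- tunnel_spec(ctr + c(off, 0, 0), jp$normal, diameter = r$d0,
                      length = cfg$tunnel_length, side = side, bundle = bundle)
    t1 <- widen_tunnel(t0, r$dw, cfg$widening_profile)
    for (tp in c("year0", "year1")) {
      tn <- if (tp == "year0") t0 else t1
      ph <- generate_phantom(spec, list(tn), seed = cfg$seed + i)
      f <- file.path(cfg$output_dir,
                     sprintf("%s_%s_%s.nii.gz", r$subject, r$tunnel, tp))
      write_mask(ph$masks[[1]], f)
      jsonlite::write_json(as.list(ph$truth[1, ]),
                           sub("\\.nii\\.gz$", "_truth.json", f),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
  }
  files
}

#' Measure tunnel masks from disk
#'
#' Reads NIfTI label masks and runs the full measurement pipeline on each.
#'
#' @param files Character vector of mask paths (as written by
#'   [simulate_study()], named `subject_tunnel_timepoint.nii.gz`).
#' @param cfg A [run_config()] (joint plane, slab width, filter constants).
#' @return A tibble of measurements, one row per mask and level, with
#'   `subject`, `tunnel`, `timepoint` parsed from the file names.
#' @export
measure_study <- function(files, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(files) == 0) abort("no mask files given")
  jp <- joint_plane(cfg$joint_plane_point, cfg$joint_plane_normal)
  purrr::map_dfr(files, function(f) {
    mask <- read_mask(f)
    pts <- mask_to_points(mask)
    m <- measure_tunnel(pts, jp, slab_halfwidth = cfg$slab_halfwidth,
                        at_depth = cfg$at_depth, k_mad = cfg$k_mad)
    parts <- strsplit(sub("\\.nii(\\.gz)?$", "", basename(f)), "_")[[1]]
    np <- length(parts)
    dplyr::mutate(tidy(m),
                  subject = parts[1],
                  tunnel = paste(parts[-c(1, np)], collapse = "_"),
                  timepoint = parts[np],
                  file = f, .before = 1)
  })
}

#' Analyze a measured cohort
#'
#' Runs the statistical layer on long-format measurements: the widening
#' and group-comparison report, the a priori power summary, and (when a
#' rater matrix is supplied) ICC(2,1) with a bootstrap CI.
#'
#' @param measurements Long-format measurement tibble (see
#'   [widening_table()]).
#' @param cfg A [run_config()].
#' @param rater_data Optional subjects x raters matrix for the
#'   reliability section.
#' @return An `analysis_result` list: `report` ([cohort_report()]),
#'   `power` (tibble), optional `icc`, and the config hash.
#' @export
analyze_study <- function(measurements, cfg = run_config(), rater_data = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  report <- cohort_report(measurements, alpha = cfg$alpha)
  power <- tibble(
    delta = 0.5, sd = 0.74, alpha = cfg$alpha, power = 0.80,
    n_required = required_sample_size(0.5, 0.74, cfg$alpha, 0.80)
  )
  icc <- NULL
  if (!is.null(rater_data)) {
    icc <- bootstrap_icc_ci(rater_data, B = cfg$bootstrap_B, seed = cfg$seed)
  }
  structure(list(report = report, power = power, icc = icc,
                 config_hash = attr(cfg, "hash"), seed = cfg$seed),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> config %s, seed %d\n\n", x$config_hash, x$seed))
  print(x$report)
  cat(sprintf("\nA priori power: n = %d patients for delta %.1f mm (sd %.2f mm)\n",
              x$power$n_required, x$power$delta, x$power$sd))
  if (!is.null(x$icc)) print(x$icc)
  invisible(x)
}

#' Write an analysis result to disk
#'
#' @param x An `analysis_result`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "analysis_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "widening_report.csv")
  p2 <- file.path(dir, "group_comparison.csv")
  p3 <- file.path(dir, "analysis.json")
  utils::write.csv(as.data.frame(x$report$widening), p1, row.names = FALSE)
  utils::write.csv(as.data.frame(x$report$comparison), p2, row.names = FALSE)
  out <- list(config_hash = x$config_hash, seed = x$seed,
              power = as.list(x$power),
              widening = x$report$widening,
              comparison = x$report$comparison)
  if (!is.null(x$icc)) {
    out$icc <- list(icc = x$icc$icc, ci_lo = x$icc$ci_lo, ci_hi = x$icc$ci_hi,
                    n_boot = x$icc$n_boot, seed = x$icc$seed)
  }
  jsonlite::write_json(out, p3, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
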