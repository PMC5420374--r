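#' Cohort widening report
#'
#' Builds the two standard report tables of a tunnel-widening study from
#' paired measurements:
#'
#' * **widening table** (one row per tunnel type x level): Year-0 and
#'   Year-1 mean +/- SD, mean widening with 95% CI in mm and in percent
#'   (per-subject percentages, integer-rounded as printed), and the
#'   paired-t p-value;
#' * **group comparison** (one row per SB-vs-DB tunnel pairing x level):
#'   widening mean +/- SD in each group and the Welch two-sample p-value.
#'
#' p-values at or above `alpha` get the label `"ns"`; exact values are
#' always retained in the `p_value` column.
#'
#' @param measurements Long-format measurement tibble (see
#'   [widening_table()]) with a `group` column.
#' @param alpha Significance level for the `"ns"` label (default 0.05).
#' @param adjust Optional p-value adjustment method for the comparison
#'   table (`"none"`, default, or `"holm"`).
#' @return A `cohort_report`: list of tibbles `widening` and
#'   `comparison`, plus the records themselves in `records`.
#' @examples
#' rep <- cohort_report(generate_cohort(cohort_spec(seed = 11)))
#' rep$widening
#' @export
cohort_report <- function(measurements, alpha = 0.05,
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  rec <- widening_table(measurements)
  if (!"group" %in% names(rec)) abort("measurements must carry a `group` column")

  widening <- rec |>
    dplyr::group_by(.data$group, .data$tunnel, .data$level) |>
    dplyr::group_modify(function(d, key) {
      tt <- paired_t(d$delta_mm)
      tp <- paired_t(d$delta_pct)
      tibble(
        n = nrow(d),
        year0_mean = mean(d$d0), year0_sd = sd(d$d0),
        year1_mean = mean(d$d1), year1_sd = sd(d$d1),
        widening_mm = tt$estimate, widening_mm_lo = tt$ci_lo,
        widening_mm_hi = tt$ci_hi,
        widening_pct = round(tp$estimate),
        widening_pct_lo = round(tp$ci_lo), widening_pct_hi = round(tp$ci_hi),
        p_value = tt$p_value
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_label = p_print(.data$p_value, alpha))

  pairings <- tibble::tribble(
    ~tunnel_sb, ~tunnel_db,
    "femur", "femur_AM",
    "femur", "femur_PL",
    "tibia", "tibia_AM",
    "tibia", "tibia_PL"
  )
  comparison <- tidyr::crossing(pairings, level = unique(rec$level)) |>
    purrr::pmap_dfr(function(tunnel_sb, tunnel_db, level) {
      a <- rec$delta_mm[rec$group == "SB" & rec$tunnel == tunnel_sb &
                          rec$level == level]
      b <- rec$delta_mm[rec$group == "DB" & rec$tunnel == tunnel_db &
                          rec$level == level]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- welch_t(a, b)
      tibble(
        level = level, tunnel_sb = tunnel_sb, tunnel_db = tunnel_db,
        sb_widening_mean = mean(a), sb_widening_sd = sd(a),
        db_widening_mean = mean(b), db_widening_sd = sd(b),
        t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value
      )
    })
  if (adjust == "holm") {
    comparison$p_value <- stats::p.adjust(comparison$p_value, "holm")
  }
  comparison <- dplyr::mutate(comparison, p_label = p_print(.data$p_value, alpha))

  structure(list(widening = widening, comparison = comparison, records = rec,
                 alpha = alpha),
            class = "cohort_report")
}

p_print <- function(p, alpha = 0.05) {
  dplyr::case_when(
    p >= alpha ~ "ns",
    p < 0.001 ~ "<0.001",
    TRUE ~ sprintf("%.3f", p)
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n\nTunnel widening Year 0 - Year 1:\n")
  print(dplyr::select(x$widening, "group", "tunnel", "level", "n",
                      "year0_mean", "year1_mean", "widening_mm",
                      "widening_pct", "p_label"), n = Inf)
  cat("\nGroup comparison (SB vs DB):\n")
  print(dplyr::select(x$comparison, "level", "tunnel_sb", "tunnel_db",
                      "sb_widening_mean", "db_widening_mean", "p_label"),
        n = Inf)
  invisible(x)
}

#' @export
tidy.cohort_report <- function(x, ...) x$widening

#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n_subjects = dplyr::n_distinct(x$records$subject),
    n_tunnels = dplyr::n_distinct(paste(x$records$group, x$records$tunnel)),
    n_levels = dplyr::n_distinct(x$records$level),
    all_significant = all(x$widening$p_value < x$alpha)
  )
}

#' Plot per-tunnel widening distributions
#'
#' @param x A `cohort_report`.
#' @param level Measurement level to show (default `"cylinder"`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cohort_report <- function(x, level = "cylinder", ...) {
  df <- dplyr::filter(x$records, .data$level == !!level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tunnel, y = .data$delta_mm,
                                   fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "widening Year1 - Year0 (mm)",
                  title = sprintf("Tunnel widening, %s level", level)) +
    ggplot2::theme_minimal()
}
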