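#' Tidy and glance methods for pipeline objects
#'
#' `tidy()` on a pipeline run returns the probe-level results; `glance()`
#' returns the one-row stage/recovery summary. On a reference panel,
#' `tidy()` returns the per-site selection statistics.
#'
#' @param x A `methdev_run` or `methdev_panel`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.methdev_run <- function(x, ...) x$probe_results

#' @rdname tidy.methdev_run
#' @export
glance.methdev_run <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "metric", values_from = "value")
}

#' @rdname tidy.methdev_run
#' @export
tidy.methdev_panel <- function(x, ...) tibble::as_tibble(x$selection)

#' @rdname tidy.methdev_run
#' @export
glance.methdev_panel <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$profile),
                 n_cell_types = length(x$cell_types))
}

#' @rdname tidy.methdev_run
#' @export
tidy.methdev_stdcurve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' Volcano plot of probe-level genotype effects
#'
#' @param probe_results Tibble from [fit_probe_models()] /
#'   [bonferroni_dmps()].
#' @return A ggplot.
#' @export
plot_volcano <- function(probe_results) {
  d <- dplyr::mutate(probe_results,
                     status = if ("is_dmp" %in% names(probe_results)) {
                       dplyr::if_else(.data$is_dmp, "DMP", "other")
                     } else "other")
  ggplot2::ggplot(d, ggplot2::aes(.data$beta_genotype,
                                  -log10(.data$p_genotype),
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(DMP = "firebrick",
                                            other = "grey40")) +
    ggplot2::labs(x = "genotype effect (beta scale, HET - WT)",
                  y = expression(-log[10](italic(P))), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of probe-level P values
#'
#' @param probe_results Tibble with `probe_id`, `p_genotype`.
#' @param manifest Probe manifest (positions).
#' @param threshold Optional horizontal significance line.
#' @return A ggplot.
#' @export
plot_manhattan <- function(probe_results, manifest, threshold = NULL) {
  d <- dplyr::inner_join(probe_results,
                         dplyr::select(manifest, "probe_id", "chrom", "pos"),
                         by = "probe_id") |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(idx = dplyr::row_number())
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$idx, -log10(.data$p_genotype),
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = "probe (genome order)",
                  y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' Pseudo-age score against chronological age
#'
#' @param scores Tibble from [score_samples()].
#' @param samples Sample sheet (joins on `sample_id`).
#' @return A ggplot.
#' @export
plot_pseudo_age <- function(scores, samples) {
  d <- dplyr::inner_join(scores, samples, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$age_days, .data$pseudo_age,
                                  colour = .data$genotype)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "age (days since E14.5)", y = "pseudo-age score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Odds ratio per threshold from an overlap sweep
#'
#' @param sweep Tibble from [threshold_sweep_overlap()].
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(factor(.data$threshold),
                                      .data$odds_ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "P threshold defining differential probes",
                  y = "odds ratio (95% CI)") +
    ggplot2::theme_minimal()
}
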