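#' Plot simulated or measured culture time courses
#'
#' Acetate, CH4 and H2 trajectories per condition; replicates are drawn as
#' thin lines.
#'
#' @param timecourses Tidy time-course tibble.
#' @return A ggplot object.
#' @examples
#' plot_timecourse(simulate_cultures(seed = 1))
#' @export
plot_timecourse <- function(timecourses) {
  long <- as_tibble(timecourses) |>
    tidyr::pivot_longer(
      c("acetate_mm", "p_ch4_atm", "p_h2_pa"),
      names_to = "analyte", values_to = "value"
    ) |>
    mutate(analyte = dplyr::recode(.data$analyte,
                                   acetate_mm = "acetate [mM]",
                                   p_ch4_atm = "CH4 [atm]",
                                   p_h2_pa = "H2 [Pa]"))
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$condition,
                                     group = interaction(.data$condition,
                                                         .data$replicate))) +
    ggplot2::geom_line(linewidth = 0.4, alpha = 0.8) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL, colour = "condition") +
    ggplot2::theme_bw()
}

#' Plot a free energy series
#'
#' Per-day replicate mean with an SD ribbon for each reaction, faceted by
#' condition; the dashed line marks the energy-conservation threshold.
#'
#' @param series A `deltag_series` from [compute_dg_series()].
#' @param threshold Threshold line, kJ/mol (defaults to the series' own).
#' @return A ggplot object.
#' @examples
#' plot_deltag(compute_dg_series(simulate_cultures(seed = 1)))
#' @export
plot_deltag <- function(series, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(series, "threshold") %||% -20
  s <- tidy(series)
  ggplot2::ggplot(s, ggplot2::aes(.data$day, .data$mean_dg_kj_mol,
                                  colour = .data$reaction,
                                  fill = .data$reaction)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_dg_kj_mol - .data$sd_dg_kj_mol,
      ymax = .data$mean_dg_kj_mol + .data$sd_dg_kj_mol),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "day", y = "dG [kJ/mol]") +
    ggplot2::theme_bw()
}

#' @rdname plot_deltag
#' @param object A `deltag_series`.
#' @param ... Unused.
#' @export
autoplot.deltag_series <- function(object, ...) plot_deltag(object)

#' Plot normalized abundances
#'
#' @param relative Output of [normalize_abundance()].
#' @return A ggplot object.
#' @examples
#' ab <- simulate_abundances(generator_config(), seed = 1)
#' plot_abundance(normalize_abundance(ab, reference = "low"))
#' @export
plot_abundance <- function(relative) {
  ggplot2::ggplot(relative,
                  ggplot2::aes(.data$condition, .data$relative_abundance,
                               fill = .data$organism)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$relative_abundance - .data$sd,
      ymax = .data$relative_abundance + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::labs(y = "16S copies relative to reference") +
    ggplot2::theme_bw()
}
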