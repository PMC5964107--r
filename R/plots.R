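#' Quadrant scatter of aerosolization factors
#'
#' A:B against A:S on log axes, one point per (taxon, day), coloured by
#' quadrant. The dashed lines at 1 separate aerosol-enriched (upper right)
#' from waterborne (lower left) taxa; a random process would scatter points
#' around (1, 1).
#'
#' @param records Tibble from [compute_enrichment()] (quadrants are added if
#'   absent).
#' @param tie_epsilon Passed to [classify_quadrant()] when quadrants are
#'   missing.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(records, tie_epsilon = 0) {
  if (!"quadrant" %in% names(records)) {
    records <- classify_quadrant(records, tie_epsilon)
  }
  df <- dplyr::filter(records, is.finite(.data$af_bulk),
                      is.finite(.data$af_ssml),
                      .data$af_bulk > 0, .data$af_ssml > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$af_bulk, y = .data$af_ssml,
                                   colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "A:B (aerosol / bulk)", y = "A:S (aerosol / SSML)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Aerosolization-factor time courses
#'
#' Per-taxon AF trajectories across sampling days on a log scale; solid
#' trajectories staying on one side of 1 are constitutive aerosolizers,
#' crossing ones intermittent.
#'
#' @param records Tibble from [compute_enrichment()].
#' @param taxa Optional character vector restricting the plot.
#' @param ratio `"af_bulk"` or `"af_ssml"`.
#' @return A ggplot object.
#' @export
plot_af_timecourse <- function(records, taxa = NULL,
                               ratio = c("af_bulk", "af_ssml")) {
  ratio <- match.arg(ratio)
  df <- collect_af_values(records, ratios = ratio)
  if (!is.null(taxa)) df <- dplyr::filter(df, .data$taxon_id %in% taxa)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$af,
                                   group = .data$taxon_id,
                                   colour = .data$taxon_id)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "experiment day",
                  y = if (ratio == "af_bulk") "A:B" else "A:S",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compartment count time series
#'
#' Concentrations by day and compartment with +/- 1 s.d. error bars.
#'
#' @param counts Counts tibble from [read_counts()].
#' @param entity Optional entity filter.
#' @return A ggplot object.
#' @export
plot_count_series <- function(counts, entity = NULL) {
  if (!is.null(entity)) counts <- counts[counts$entity == entity, ]
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$day, y = .data$value,
                                       colour = .data$compartment)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~entity, scales = "free_y") +
    ggplot2::labs(x = "experiment day",
                  y = expression("concentration (" * 10^7 * " per mL)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname compare_domains
#' @param object A `domain_comparison`.
#' @export
autoplot.domain_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_day,
                  ggplot2::aes(x = .data$day, y = .data$mean_af,
                               colour = .data$domain)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "experiment day", y = "mean AF", colour = NULL) +
    ggplot2::theme_minimal()
}
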