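#' Plot a recombination map
#'
#' Cumulative genetic position against physical position per chromosome,
#' one line per population — the classic genetic-vs-physical "S-curves"
#' whose flat centres are the recombination-poor pericentromeric regions.
#'
#' @param object `xomap_map` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot xomap_map
#' @export
autoplot.xomap_map <- function(object, ...) {
  df <- object$intervals |>
    dplyr::group_by(.data$population, .data$chrom) |>
    dplyr::arrange(.data$left_bp, .by_group = TRUE) |>
    dplyr::mutate(cum_cm = cumsum(.data$d_cm)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$right_bp / 1e6,
                                   y = .data$cum_cm,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "Physical position (Mbp)",
                  y = "Cumulative genetic distance (cM)",
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' Plot a binned recombination landscape
#'
#' Genome-wide recombination by relative physical position: the per-bin
#' totals summed across chromosomes, one line per population.
#'
#' @param object `xomap_landscape` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot xomap_landscape
#' @export
autoplot.xomap_landscape <- function(object, ...) {
  ylab <- if (object$weight == "cm") "Recombination (cM)" else
    "Crossover events"
  ggplot2::ggplot(object$genome,
                  ggplot2::aes(x = .data$bin / object$n_bins * 100,
                               y = .data$value,
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Relative physical position (%)", y = ylab,
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' Plot zone summaries
#'
#' Total recombination per genomic zone and population as grouped bars.
#'
#' @param zone_summary Tibble from [zone_summaries()].
#' @param weight Plot `"cm"` totals or `"events"` counts.
#' @return A ggplot object.
#' @export
plot_zone_summary <- function(zone_summary, weight = c("cm", "events")) {
  weight <- match.arg(weight)
  y <- if (weight == "cm") "cm" else "n_events"
  ggplot2::ggplot(zone_summary,
                  ggplot2::aes(x = factor(.data$zone), y = .data[[y]],
                               fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Genomic zone",
                  y = if (weight == "cm") "Recombination (cM)" else
                    "Crossover events",
                  fill = "Population") +
    ggplot2::theme_minimal()
}
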