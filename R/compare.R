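#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided Wilcoxon signed-rank test on paired values (typically
#' per-chromosome map lengths of two populations; chromosomes are the
#' natural exchangeable pairing unit). Zero differences are dropped. The
#' exact signed-rank distribution is used for up to `exact_max` informative
#' pairs when the absolute differences are free of ties; otherwise the
#' normal approximation with continuity correction is used.
#'
#' @param values_a,values_b Equal-length paired numeric vectors.
#' @param comparison Optional label stored in the result.
#' @param exact_max Largest number of pairs for which the exact distribution
#'   is used.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble: `comparison`, `n_pairs`, `statistic`, `p_value`,
#'   `method`, `significant`.
#' @export
wilcoxon_paired <- function(values_a, values_b, comparison = "a vs b",
                            exact_max = 25, alpha = 0.05) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) {
    abort("No informative pairs: all differences are zero or missing.")
  }
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  tibble::tibble(
    comparison = comparison,
    n_pairs = length(d),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation",
    significant = wt$p.value < alpha
  )
}

#' Compare genome map lengths of two populations
#'
#' Builds paired per-unit centiMorgan totals (per chromosome, or per
#' chromosome and zone) for two populations of a fitted map and runs
#' [wilcoxon_paired()].
#'
#' @param rec_map `xomap_map` object containing both populations.
#' @param pop_a,pop_b Population labels.
#' @param unit `"chromosome"` pairs per-chromosome totals;
#'   `"chromosome_zone"` pairs per chromosome-by-zone totals (requires
#'   `zone_scheme`).
#' @param zone_scheme Zone scheme, needed for `unit = "chromosome_zone"`.
#' @param zones Restrict the zone pairing to these zones.
#' @return One-row comparison tibble (see [wilcoxon_paired()]).
#' @export
compare_map_lengths <- function(rec_map, pop_a, pop_b,
                                unit = c("chromosome", "chromosome_zone"),
                                zone_scheme = NULL, zones = 1:3) {
  unit <- match.arg(unit)
  iv <- rec_map$intervals
  if (!all(c(pop_a, pop_b) %in% iv$population)) {
    abort("Both populations must be present in the map.")
  }
  if (unit == "chromosome") {
    wide <- iv |>
      dplyr::group_by(.data$population, .data$chrom) |>
      dplyr::summarise(cm = sum(.data$d_cm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "population", values_from = "cm",
                         values_fill = 0)
  } else {
    if (is.null(zone_scheme)) {
      abort("`zone_scheme` is required for unit = \"chromosome_zone\".")
    }
    mid <- floor((iv$left_bp + iv$right_bp) / 2)
    wide <- iv |>
      dplyr::mutate(zone = assign_zone(mid, iv$chrom, zone_scheme)) |>
      dplyr::filter(.data$zone %in% zones) |>
      dplyr::group_by(.data$population, .data$chrom, .data$zone) |>
      dplyr::summarise(cm = sum(.data$d_cm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "population", values_from = "cm",
                         values_fill = 0)
  }
  wilcoxon_paired(wide[[pop_a]], wide[[pop_b]],
                  comparison = paste(pop_a, "vs", pop_b))
}

#' Chi-squared test on zone proportions
#'
#' Pearson chi-squared test (no continuity correction) on a 2 x k
#' contingency table of crossover-event counts per zone for two
#' populations. The default comparison is the distal vs interstitial
#' (zone 1 vs zone 2) share, the compartments where recombination actually
#' occurs.
#'
#' @param zone_counts_a,zone_counts_b Numeric vectors of event counts per
#'   zone (same zones, same order), e.g. from [zone_summaries()].
#' @param comparison Optional label.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble with `statistic` (X-squared), `df`, `p_value`.
#'   A warning is raised when any expected cell count is below 1.
#' @export
chisq_zone_proportions <- function(zone_counts_a, zone_counts_b,
                                   comparison = "a vs b", alpha = 0.05) {
  stopifnot(length(zone_counts_a) == length(zone_counts_b))
  tab <- rbind(zone_counts_a, zone_counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warn("Expected cell count below 1; chi-squared approximation is poor.")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    comparison = comparison,
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    significant = ct$p.value < alpha
  )
}

#' Welch t-test on fertility
#'
#' Computes each plant's percent fertile florets (mean over its scored
#' ears of `100 fertile_seeds / total_florets`) and compares two
#' populations with a two-sided Welch t-test.
#'
#' @param fertility Fertility tibble (`individual_id`, `population`,
#'   `fertile_seeds`, `total_florets`; one row per ear).
#' @param group_a,group_b Population labels to compare.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble with group means, `statistic` (t), `df`,
#'   `p_value`, `significant`.
#' @export
fertility_ttest <- function(fertility, group_a, group_b, alpha = 0.05) {
  per_plant <- fertility |>
    dplyr::group_by(.data$individual_id, .data$population) |>
    dplyr::summarise(
      pct_fertile = mean(100 * .data$fertile_seeds / .data$total_florets),
      .groups = "drop"
    )
  x <- per_plant$pct_fertile[per_plant$population == group_a]
  y <- per_plant$pct_fertile[per_plant$population == group_b]
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 plants.")
  }
  tt <- stats::t.test(x, y)
  tibble::tibble(
    comparison = paste(group_a, "vs", group_b),
    mean_a = mean(x), mean_b = mean(y),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha
  )
}
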