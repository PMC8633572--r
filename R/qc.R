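#' QC configuration
#'
#' Thresholds for the pre-calling filters. Defaults follow common practice
#' for biparental array data: markers with more than 5% missing calls are
#' dropped (strict inequality), markers whose minor allele frequency falls
#' below 0.10 are considered ambiguous/skewed (the F2/F3 expectation is
#' 0.5, so this removes only gross distortions), and individuals whose
#' preliminary genome-wide validated crossover count exceeds 35 are treated
#' as artifact-laden and discarded.
#'
#' @param max_marker_missing Maximum tolerated missing-call fraction per
#'   marker; markers strictly above are removed.
#' @param skew_min_minor_freq Minimum minor allele frequency, computed as
#'   `min(f, 1 - f)` with `f = (2 nA + nH) / (2 (nA + nH + nB))`.
#' @param max_individual_co Maximum preliminary crossover count per
#'   individual (validated caller, no family masking); `Inf` disables.
#' @param drop_monomorphic Remove markers whose non-missing calls are all
#'   identical.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_marker_missing = 0.05,
                      skew_min_minor_freq = 0.10,
                      max_individual_co = 35,
                      drop_monomorphic = TRUE) {
  stopifnot(max_marker_missing >= 0, max_marker_missing <= 1,
            skew_min_minor_freq >= 0, skew_min_minor_freq <= 1,
            max_individual_co >= 0)
  structure(list(max_marker_missing = max_marker_missing,
                 skew_min_minor_freq = skew_min_minor_freq,
                 max_individual_co = max_individual_co,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_config")
}

drop_markers <- function(genotypes, ids) {
  genotypes[setdiff(names(genotypes), ids)]
}

#' Remove monomorphic markers
#'
#' Drops markers whose non-missing calls are all identical (including
#' markers with no non-missing call at all).
#'
#' @param genotypes Genotype tibble.
#' @return List with `genotypes` (filtered) and `removed` (marker ids).
#' @export
filter_monomorphic <- function(genotypes) {
  mat <- geno_matrix(genotypes)
  n_states <- apply(mat, 2, function(col) length(unique(col[!is.na(col)])))
  removed <- colnames(mat)[n_states <= 1L]
  list(genotypes = drop_markers(genotypes, removed), removed = removed)
}

#' Remove markers with skewed allele frequencies
#'
#' The A-allele frequency of a marker is `(2 nA + nH) / (2 (nA + nH + nB))`;
#' markers whose minor allele frequency is strictly below
#' `skew_min_minor_freq` are removed. Markers with no non-missing calls are
#' removed as well.
#'
#' @param genotypes Genotype tibble.
#' @param skew_min_minor_freq Threshold; `0` removes nothing.
#' @return List with `genotypes` and `removed`.
#' @export
filter_skewed <- function(genotypes, skew_min_minor_freq = 0.10) {
  mat <- geno_matrix(genotypes)
  n_a <- colSums(mat == "A", na.rm = TRUE)
  n_h <- colSums(mat == "H", na.rm = TRUE)
  n_b <- colSums(mat == "B", na.rm = TRUE)
  tot <- n_a + n_h + n_b
  freq <- ifelse(tot > 0, (2 * n_a + n_h) / (2 * tot), NA_real_)
  maf <- pmin(freq, 1 - freq)
  removed <- colnames(mat)[is.na(maf) | maf < skew_min_minor_freq]
  if (skew_min_minor_freq == 0) removed <- colnames(mat)[is.na(maf)]
  list(genotypes = drop_markers(genotypes, removed), removed = removed)
}

#' Remove markers with too much missing data
#'
#' @param genotypes Genotype tibble.
#' @param max_marker_missing Markers with missing fraction strictly greater
#'   than this are removed (5 missing in 100 is retained at the 0.05
#'   default; 6 is removed).
#' @return List with `genotypes` and `removed`.
#' @export
filter_missing <- function(genotypes, max_marker_missing = 0.05) {
  mat <- geno_matrix(genotypes)
  frac <- colMeans(is.na(mat))
  removed <- colnames(mat)[frac > max_marker_missing]
  list(genotypes = drop_markers(genotypes, removed), removed = removed)
}

#' Remove hyper-recombinant individuals
#'
#' Isolated miscalls inflate naive crossover counts; individuals carrying an
#' abundance of them stand out by their genome-wide count even under the
#' validated caller. This filter computes a preliminary validated crossover
#' count per individual with no family masking (every marker treated as
#' informative) and removes individuals whose count exceeds
#' `max_individual_co`.
#'
#' @param genotypes Genotype tibble after the marker filters.
#' @param marker_map Marker map.
#' @param max_individual_co Count threshold (strict `>`); `Inf` disables.
#' @param config Caller configuration used for the preliminary counts.
#' @return List with `genotypes`, `removed` (tibble `individual_id`, `n_co`
#'   of the removed individuals) and `counts` (all preliminary counts).
#' @export
filter_hyperrecombinant <- function(genotypes, marker_map,
                                    max_individual_co = 35,
                                    config = co_caller_config()) {
  events <- call_crossovers(genotypes, marker_map, masks = NULL,
                            config = config)
  counts <- count_crossovers(events, genotypes)
  removed <- dplyr::filter(counts, .data$n_co > max_individual_co)
  keep <- dplyr::filter(genotypes,
                        !.data$individual_id %in% removed$individual_id)
  list(genotypes = keep, removed = removed, counts = counts)
}

#' Run the full QC pipeline
#'
#' Applies the filters in a fixed order: monomorphic markers, skewed
#' markers, markers with excess missing data, then hyper-recombinant
#' individuals. Removing individuals can newly create monomorphic or skewed
#' markers, so the marker filters are applied once more afterwards; a third
#' pass is asserted to be a no-op (marker statistics are per-column, so one
#' extra pass always converges).
#'
#' @param genotypes Genotype tibble (A/H/B calls).
#' @param marker_map Marker map covering the genotype markers.
#' @param config A [qc_config()].
#' @param caller_config Caller configuration for the preliminary counts.
#' @return A list of class `xomap_qc`: `genotypes` (the retained table),
#'   and `report`, a list with per-rule marker removals, removed individuals
#'   with their preliminary counts, and retained totals.
#' @export
run_qc <- function(genotypes, marker_map, config = qc_config(),
                   caller_config = co_caller_config()) {
  assert_genotypes(genotypes)
  n_markers_in <- length(marker_cols(genotypes))
  n_ind_in <- nrow(genotypes)

  pass <- function(g) {
    mono <- if (config$drop_monomorphic) filter_monomorphic(g) else
      list(genotypes = g, removed = character())
    skew <- filter_skewed(mono$genotypes, config$skew_min_minor_freq)
    miss <- filter_missing(skew$genotypes, config$max_marker_missing)
    list(genotypes = miss$genotypes, monomorphic = mono$removed,
         skewed = skew$removed, missing = miss$removed)
  }

  p1 <- pass(genotypes)
  hyper <- filter_hyperrecombinant(p1$genotypes, marker_map,
                                   config$max_individual_co, caller_config)
  p2 <- pass(hyper$genotypes)
  p3 <- pass(p2$genotypes)
  n_p3 <- length(p3$monomorphic) + length(p3$skewed) + length(p3$missing)
  if (n_p3 > 0) {
    abort("Marker filters did not converge after individual removal.")
  }

  out <- p2$genotypes
  report <- list(
    markers_removed = list(
      monomorphic = c(p1$monomorphic, p2$monomorphic),
      skewed = c(p1$skewed, p2$skewed),
      missing = c(p1$missing, p2$missing)
    ),
    individuals_removed = hyper$removed,
    preliminary_co_counts = hyper$counts,
    n_markers_in = n_markers_in,
    n_markers_retained = length(marker_cols(out)),
    n_individuals_in = n_ind_in,
    n_individuals_retained = nrow(out)
  )
  n_rm <- sum(lengths(report$markers_removed))
  stopifnot(report$n_markers_retained + n_rm == n_markers_in,
            report$n_individuals_retained + nrow(hyper$removed) == n_ind_in)
  structure(list(genotypes = out, report = report), class = "xomap_qc")
}

#' @export
print.xomap_qc <- function(x, ...) {
  r <- x$report
  cat("Genotype QC\n")
  cat(sprintf("  markers:     %d in, %d retained (%d monomorphic, %d skewed, %d missing-data)\n",
              r$n_markers_in, r$n_markers_retained,
              length(r$markers_removed$monomorphic),
              length(r$markers_removed$skewed),
              length(r$markers_removed$missing)))
  cat(sprintf("  individuals: %d in, %d retained (%d hyper-recombinant removed)\n",
              r$n_individuals_in, r$n_individuals_retained,
              nrow(r$individuals_removed)))
  invisible(x)
}

#' @method tidy xomap_qc
#' @export
tidy.xomap_qc <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    rule = c("monomorphic", "skewed", "missing", "hyperrecombinant"),
    axis = c("marker", "marker", "marker", "individual"),
    n_removed = c(length(r$markers_removed$monomorphic),
                  length(r$markers_removed$skewed),
                  length(r$markers_removed$missing),
                  nrow(r$individuals_removed))
  )
}

#' @method glance xomap_qc
#' @export
glance.xomap_qc <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_markers_in = r$n_markers_in,
    n_markers_retained = r$n_markers_retained,
    n_individuals_in = r$n_individuals_in,
    n_individuals_retained = r$n_individuals_retained
  )
}
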