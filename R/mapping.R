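#' Kosambi map function
#'
#' Converts a recombination fraction to a Kosambi map distance,
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centiMorgans, and back
#' (`r = tanh(2d / 100) / 2`). The Kosambi function accounts for moderate
#' crossover interference; for small `r` it approaches `d = 100 r`.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @param d_cm Map distance(s) in centiMorgans, `d >= 0`.
#' @return `kosambi_cm()`: distances in cM; `kosambi_r()`: fractions.
#' @export
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0 | r >= 0.5)) {
    abort("Kosambi distance requires 0 <= r < 0.5.")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d_cm) {
  if (any(is.na(d_cm)) || any(d_cm < 0)) {
    abort("Map distances must be non-negative.")
  }
  tanh(2 * d_cm / 100) / 2
}

#' Interval recombination fractions
#'
#' Computes, per population and per pair of map-adjacent markers, the
#' recombination fraction `r = n_events / n_informative` and its Kosambi
#' distance.
#'
#' Two assignment conventions are available. With `"midpoint"`, each event
#' contributes its multiplicity to the interval containing its physical
#' midpoint, and an individual counts toward an interval's denominator only
#' when both flanking markers are informative for its family and
#' non-missing; intervals nobody is informative for are omitted, and events
#' whose midpoint falls in such an interval are dropped with a warning.
#' This is the classical convention and is exact when every family is
#' informative at (nearly) every marker. When families carry wide
#' uninformative blocks (e.g. a parental F2 homozygous across the
#' pericentromere), events detected across such a block all share one
#' midpoint while the denominator there counts only the families that are
#' informative at those exact central markers: the numerator and
#' denominator then refer to different sets of individuals, and the convex
#' Kosambi transform amplifies the spuriously concentrated fractions. The
#' `"span"` convention avoids this: each event's multiplicity is spread
#' over the map intervals covered by its flanking-marker span,
#' proportionally to physical length, and an individual counts toward an
#' interval's denominator whenever its informative non-missing span covers
#' the interval. Numerator and denominator then always refer to the same
#' individuals, `n_events` may be fractional, and the two conventions
#' coincide for events whose flanks are map-adjacent.
#'
#' @param events Event tibble from [call_crossovers()].
#' @param genotypes The genotype tibble the events were called from.
#' @param marker_map Marker map covering the genotype markers.
#' @param masks Mask tibble from [build_family_masks()], or `NULL` for
#'   all-informative.
#' @param event_assignment `"midpoint"` (classical; default) or `"span"`
#'   (recommended when family informativeness is blocky); see Details.
#' @param on_high_r What to do with intervals whose estimated `r` reaches
#'   0.5, where the Kosambi transform is undefined: `"error"` (default)
#'   stops and names them; `"drop"` excludes them with a warning — the
#'   programmatic analog of hand-curating artifact intervals.
#' @return Tibble with `population`, `chrom`, `left_marker`, `right_marker`,
#'   `left_bp`, `right_bp`, `n_events`, `n_informative`, `r`, `d_cm`.
#' @export
interval_recombination_fractions <- function(events, genotypes, marker_map,
                                             masks = NULL,
                                             event_assignment = c("midpoint",
                                                                  "span"),
                                             on_high_r = c("error", "drop")) {
  event_assignment <- match.arg(event_assignment)
  on_high_r <- match.arg(on_high_r)
  assert_genotypes(genotypes)
  mm <- map_for_genotypes(marker_map, genotypes) |>
    dplyr::arrange(.data$chrom, .data$pos_bp)
  mat <- geno_matrix(genotypes)[, mm$marker_id, drop = FALSE]

  # informative & non-missing indicator, individuals x markers
  ok <- !is.na(mat)
  if (!is.null(masks)) {
    mask_lookup <- split(masks$marker_id, masks$family_id)
    for (i in seq_len(nrow(mat))) {
      fam <- genotypes$family_id[i]
      ok[i, ] <- ok[i, ] & (mm$marker_id %in% mask_lookup[[fam]])
    }
  }

  pops <- if ("population" %in% names(genotypes)) {
    genotypes$population
  } else {
    rep("all", nrow(genotypes))
  }
  ev_pop <- if ("population" %in% names(events) && nrow(events) > 0) {
    events$population
  } else {
    rep("all", nrow(events))
  }

  by_chrom <- split(seq_len(nrow(mm)), mm$chrom)
  res <- list()
  n_dropped <- 0L
  for (pop in unique(pops)) {
    rows <- which(pops == pop)
    ev <- events[ev_pop == pop, , drop = FALSE]
    for (chr in names(by_chrom)) {
      idx <- by_chrom[[chr]]
      if (length(idx) < 2L) next
      sub <- ok[rows, idx, drop = FALSE]
      pos <- mm$pos_bp[idx]
      n_pairs <- length(idx) - 1L
      evc <- ev[ev$chrom == chr, , drop = FALSE]
      n_ev <- numeric(n_pairs)
      if (event_assignment == "midpoint") {
        n_inf <- colSums(sub[, -ncol(sub), drop = FALSE] &
                           sub[, -1L, drop = FALSE])
        if (nrow(evc)) {
          j <- findInterval(evc$midpoint_bp, pos, rightmost.closed = TRUE)
          j[j >= length(pos)] <- length(pos) - 1L
          valid <- j >= 1L
          agg <- tapply(evc$multiplicity[valid], j[valid], sum)
          n_ev[as.integer(names(agg))] <- agg
        }
      } else {
        # span: spread each event over the pairs its flanks cover, and
        # count an individual wherever its informative span covers the pair
        n_inf <- numeric(n_pairs)
        for (i in seq_len(nrow(sub))) {
          at <- which(sub[i, ])
          if (length(at) < 2L) next
          n_inf[at[1]:(at[length(at)] - 1L)] <-
            n_inf[at[1]:(at[length(at)] - 1L)] + 1
        }
        if (nrow(evc)) {
          jl <- match(evc$left_bp, pos)
          jr <- match(evc$right_bp, pos)
          width <- diff(pos)
          for (e in seq_len(nrow(evc))) {
            span <- jl[e]:(jr[e] - 1L)
            n_ev[span] <- n_ev[span] +
              evc$multiplicity[e] * width[span] / sum(width[span])
          }
        }
      }
      keep <- n_inf >= 1
      n_dropped <- n_dropped + sum(n_ev[!keep] > 0)
      res[[paste(pop, chr)]] <- tibble::tibble(
        population = pop,
        chrom = chr,
        left_marker = mm$marker_id[idx][-length(idx)][keep],
        right_marker = mm$marker_id[idx][-1L][keep],
        left_bp = pos[-length(pos)][keep],
        right_bp = pos[-1L][keep],
        n_events = n_ev[keep],
        n_informative = as.integer(n_inf[keep])
      )
    }
  }
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " event(s) fell in interval(s) with no ",
                "informative individuals and were dropped."))
  }
  if (!length(res)) {
    return(tibble::tibble(population = character(), chrom = character(),
                          left_marker = character(),
                          right_marker = character(),
                          left_bp = numeric(), right_bp = numeric(),
                          n_events = numeric(), n_informative = integer(),
                          r = numeric(), d_cm = numeric()))
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(r = .data$n_events / .data$n_informative)
  high <- dplyr::filter(out, .data$r >= 0.5)
  if (nrow(high)) {
    what <- paste(utils::head(paste0(high$population, ":", high$left_marker,
                                     "-", high$right_marker), 5),
                  collapse = ", ")
    if (on_high_r == "error") {
      abort(paste0("Recombination fraction >= 0.5 (Kosambi undefined) in ",
                   "interval(s): ", what))
    }
    warn(paste0(nrow(high), " interval(s) with r >= 0.5 dropped ",
                "(Kosambi undefined): ", what))
    out <- dplyr::filter(out, .data$r < 0.5)
  }
  dplyr::mutate(out, d_cm = kosambi_cm(.data$r))
}

#' Genetic map lengths
#'
#' Sums Kosambi interval distances into per-chromosome and genome map
#' lengths per population, and converts genome length to crossover
#' equivalents per selfed F2 individual. A selfed individual unites two
#' meiotic products, so the genome length in centiMorgans is divided by 50
#' (not 100) and reported to one decimal, matching the convention of
#' per-individual recombination fractions.
#'
#' @param intervals Interval tibble from
#'   [interval_recombination_fractions()].
#' @return An object of class `xomap_map`: list with `intervals`,
#'   `chromosomes` (per-population, per-chromosome cM) and `genome`
#'   (per-population total cM and `co_equivalents`).
#' @export
map_lengths <- function(intervals) {
  if (nrow(intervals) == 0) {
    chromosomes <- tibble::tibble(population = character(),
                                  chrom = character(), cm = numeric())
    genome <- tibble::tibble(population = character(), total_cm = numeric(),
                             co_equivalents = numeric())
  } else {
    chromosomes <- intervals |>
      dplyr::group_by(.data$population, .data$chrom) |>
      dplyr::summarise(cm = sum(.data$d_cm), .groups = "drop")
    genome <- chromosomes |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(total_cm = sum(.data$cm), .groups = "drop") |>
      dplyr::mutate(co_equivalents = co_equivalents(.data$total_cm))
  }
  structure(list(intervals = intervals, chromosomes = chromosomes,
                 genome = genome),
            class = "xomap_map")
}

#' Crossover equivalents of a genome map length
#'
#' @param total_cm Genome map length(s) in centiMorgans (per-individual
#'   convention).
#' @return `total_cm / 50`, rounded to one decimal: the expected crossover
#'   count per selfed F2 individual (two meioses).
#' @export
co_equivalents <- function(total_cm) {
  round(total_cm / 50, 1)
}

#' Percent change between two map lengths
#'
#' Reports both conventions seen in the literature: the percent change
#' `100 (a - b) / b` and the plain ratio expressed as a percentage
#' `100 a / b`.
#'
#' @param cm_a,cm_b Genome map lengths in cM (scalars), or `xomap_map`
#'   objects with a single population each.
#' @return Tibble with `cm_a`, `cm_b`, `pct_change`, `ratio_pct`.
#' @export
percent_change <- function(cm_a, cm_b) {
  if (inherits(cm_a, "xomap_map")) cm_a <- sum(cm_a$genome$total_cm)
  if (inherits(cm_b, "xomap_map")) cm_b <- sum(cm_b$genome$total_cm)
  if (cm_b == 0) abort("Reference map length is zero; percent change undefined.")
  tibble::tibble(cm_a = cm_a, cm_b = cm_b,
                 pct_change = 100 * (cm_a - cm_b) / cm_b,
                 ratio_pct = 100 * cm_a / cm_b)
}

#' @export
print.xomap_map <- function(x, ...) {
  cat("Recombination map\n")
  if (nrow(x$genome) == 0) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  g <- x$genome
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-10s %8.1f cM  (%.1f CO equivalents)\n",
                g$population[i], g$total_cm[i], g$co_equivalents[i]))
  }
  invisible(x)
}

#' @method tidy xomap_map
#' @export
tidy.xomap_map <- function(x, ...) {
  x$chromosomes
}

#' @method glance xomap_map
#' @export
glance.xomap_map <- function(x, ...) {
  x$genome
}
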