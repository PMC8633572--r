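#' Assign physical positions to genomic zones
#'
#' Looks each position up in the zone scheme's segments (half-open
#' `[start_bp, end_bp)`; a position equal to the chromosome end falls in the
#' last segment). Positions outside the covered range raise an error.
#'
#' @param pos_bp Numeric vector of positions.
#' @param chrom Chromosome of each position (recycled if length 1).
#' @param zone_scheme Zone scheme tibble (see [read_zone_scheme()]).
#' @return Integer vector of zones (1 distal, 2 interstitial,
#'   3 pericentromeric).
#' @export
assign_zone <- function(pos_bp, chrom, zone_scheme) {
  validate_zone_scheme(zone_scheme)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos_bp))
  stopifnot(length(chrom) == length(pos_bp))
  out <- integer(length(pos_bp))
  for (chr in unique(chrom)) {
    zs <- zone_scheme[zone_scheme$chrom == chr, , drop = FALSE]
    if (nrow(zs) == 0) abort(paste0("Chromosome not in zone scheme: ", chr))
    sel <- chrom == chr
    p <- pos_bp[sel]
    L <- max(zs$end_bp)
    if (any(p < 0 | p > L)) {
      abort(paste0("Position outside chromosome ", chr, " [0, ", L, "]."))
    }
    j <- findInterval(p, zs$start_bp, rightmost.closed = FALSE)
    j[p >= L] <- nrow(zs)
    out[sel] <- zs$zone[j]
  }
  out
}

#' Bin the recombination landscape into fixed physical fractions
#'
#' Divides every chromosome into `n_bins` bins of equal physical width
#' (edges at `i L / n_bins`, half-open with the final bin closed) and sums
#' into each bin the Kosambi centiMorgans (or, optionally, the event
#' counts) of the intervals whose crossover midpoint falls inside it. Bins
#' are also aggregated genome-wide by bin index, i.e. by relative physical
#' position, so chromosomes of unequal length line up.
#'
#' @param intervals Interval tibble from
#'   [interval_recombination_fractions()].
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or
#'   a tibble with `chrom` and `length_bp` (see [chromosome_lengths()]).
#' @param n_bins Number of bins per chromosome (50 gives ~2% bins).
#' @param weight `"cm"` bins map distance, `"events"` bins event counts.
#' @return Object of class `xomap_landscape`: list with `bins`
#'   (`population`, `chrom`, `bin`, `start_bp`, `end_bp`, `value`) and
#'   `genome` (`population`, `bin`, `value` summed across chromosomes).
#' @export
bin_landscape <- function(intervals, chrom_lengths, n_bins = 50,
                          weight = c("cm", "events")) {
  weight <- match.arg(weight)
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  }
  val <- if (weight == "cm") intervals$d_cm else intervals$n_events
  mid <- floor((intervals$left_bp + intervals$right_bp) / 2)
  res <- list()
  for (chr in unique(intervals$chrom)) {
    if (!chr %in% names(chrom_lengths)) {
      abort(paste0("No chromosome length for ", chr, "."))
    }
    L <- chrom_lengths[[chr]]
    sel <- which(intervals$chrom == chr)
    if (any(mid[sel] < 0 | mid[sel] > L)) {
      abort(paste0("Interval midpoint outside chromosome ", chr, "."))
    }
    edges <- seq(0, L, length.out = n_bins + 1)
    bin <- findInterval(mid[sel], edges, rightmost.closed = TRUE)
    grid <- tidyr::expand_grid(
      population = unique(intervals$population[sel]),
      bin = seq_len(n_bins)
    )
    agg <- tibble::tibble(population = intervals$population[sel],
                          bin = bin, value = val[sel]) |>
      dplyr::group_by(.data$population, .data$bin) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
    res[[chr]] <- grid |>
      dplyr::left_join(agg, by = c("population", "bin")) |>
      dplyr::mutate(value = dplyr::coalesce(.data$value, 0),
                    chrom = chr,
                    start_bp = edges[.data$bin],
                    end_bp = edges[.data$bin + 1L])
  }
  bins <- dplyr::bind_rows(res) |>
    dplyr::select("population", "chrom", "bin", "start_bp", "end_bp",
                  "value") |>
    dplyr::arrange(.data$population, .data$chrom, .data$bin)
  genome <- bins |>
    dplyr::group_by(.data$population, .data$bin) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  structure(list(bins = bins, genome = genome, weight = weight,
                 n_bins = n_bins),
            class = "xomap_landscape")
}

#' Summarise recombination by genomic zone
#'
#' Assigns every interval to a zone by its crossover midpoint (an interval
#' straddling a boundary is assigned wholly by the midpoint) and totals
#' centiMorgans and event counts per population and zone, together with
#' each zone's share.
#'
#' @param intervals Interval tibble from
#'   [interval_recombination_fractions()].
#' @param zone_scheme Zone scheme tibble.
#' @return Tibble with `population`, `zone`, `cm`, `n_events`, `prop_cm`,
#'   `prop_events` (zones absent from the data appear with zeros).
#' @export
zone_summaries <- function(intervals, zone_scheme) {
  mid <- floor((intervals$left_bp + intervals$right_bp) / 2)
  zone <- assign_zone(mid, intervals$chrom, zone_scheme)
  tibble::tibble(population = intervals$population, zone = zone,
                 cm = intervals$d_cm, n_events = intervals$n_events) |>
    dplyr::group_by(.data$population, .data$zone) |>
    dplyr::summarise(cm = sum(.data$cm), n_events = sum(.data$n_events),
                     .groups = "drop") |>
    tidyr::complete(.data$population, zone = 1:3,
                    fill = list(cm = 0, n_events = 0)) |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(prop_cm = .data$cm / sum(.data$cm),
                  prop_events = .data$n_events / sum(.data$n_events)) |>
    dplyr::ungroup() |>
    dplyr::mutate(dplyr::across(c("prop_cm", "prop_events"),
                                ~ifelse(is.nan(.x), NA_real_, .x)))
}

#' Chromosome lengths of a zone scheme
#'
#' @param zone_scheme Zone scheme tibble.
#' @return Tibble with `chrom` and `length_bp` (the end of the last
#'   segment).
#' @export
chromosome_lengths <- function(zone_scheme) {
  zone_scheme |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length_bp = max(.data$end_bp), .groups = "drop")
}

#' @export
print.xomap_landscape <- function(x, ...) {
  cat(sprintf("Recombination landscape: %d bins per chromosome, %s-weighted\n",
              x$n_bins, x$weight))
  print(x$genome, n = 5)
  invisible(x)
}

#' @method tidy xomap_landscape
#' @export
tidy.xomap_landscape <- function(x, ...) {
  x$bins
}
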