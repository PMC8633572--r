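#' Match called events against simulated truth
#'
#' Classifies each called crossover event as a true positive when a real
#' crossover explains it, and reports the observable true crossovers the
#' caller missed. An event is explained by (a) a true F2-meiosis crossover
#' of the same individual lying inside the called interval, or (b) a
#' family-level phase flip (a crossover in the same interval in both F1
#' gametes, which swaps the phase of the F2's haplotypes and produces
#' genuine hom-to-hom switches in its homozygous F3s) overlapping the
#' called interval; matches are labelled by origin. The interval can be
#' widened by `tolerance` markers on each side.
#'
#' @param events Event tibble from [call_crossovers()] run on simulated
#'   genotypes.
#' @param truth `xomap_truth` object from [simulate_pedigree()].
#' @param marker_map Marker map; required when `tolerance > 0`.
#' @param tolerance Number of markers by which to extend each event
#'   interval on each side before matching.
#' @return List with `summary` (one-row tibble: `n_events`, `tp`, `fp`,
#'   `n_observable`, `missed`) and `events` (the input events plus
#'   `matched` and `origin`).
#' @export
truth_match <- function(events, truth, marker_map = NULL, tolerance = 0) {
  stopifnot(inherits(truth, "xomap_truth"))
  n_obs <- sum(truth$co$observable)
  if (nrow(events) == 0L) {
    return(list(
      summary = tibble::tibble(n_events = 0L, tp = 0L, fp = 0L,
                               n_observable = n_obs, missed = n_obs),
      events = dplyr::mutate(events, matched = logical(0),
                             origin = character(0))
    ))
  }
  lo <- events$left_bp
  hi <- events$right_bp
  if (tolerance > 0) {
    if (is.null(marker_map)) {
      abort("`marker_map` is required when tolerance > 0.")
    }
    mm <- dplyr::arrange(marker_map, .data$chrom, .data$pos_bp)
    for (i in seq_len(nrow(events))) {
      pos <- mm$pos_bp[mm$chrom == events$chrom[i]]
      li <- findInterval(lo[i], pos)
      ri <- findInterval(hi[i] - 1, pos) + 1L
      lo[i] <- pos[max(1L, li - tolerance)]
      hi[i] <- pos[min(length(pos), ri + tolerance)]
    }
  }

  co <- truth$co
  flips <- truth$phase_flips
  matched <- logical(nrow(events))
  origin <- rep(NA_character_, nrow(events))
  co_hit <- logical(nrow(co))
  for (i in seq_len(nrow(events))) {
    hit <- which(co$individual_id == events$individual_id[i] &
                   co$chrom == events$chrom[i] &
                   co$pos_bp >= lo[i] & co$pos_bp <= hi[i])
    if (length(hit)) {
      matched[i] <- TRUE
      origin[i] <- "f2_meiosis"
      co_hit[hit] <- TRUE
      next
    }
    fhit <- flips$family_id == events$family_id[i] &
      flips$chrom == events$chrom[i] &
      flips$left_bp < hi[i] & flips$right_bp > lo[i]
    if (any(fhit)) {
      matched[i] <- TRUE
      origin[i] <- "f1_phase_flip"
    }
  }
  missed <- sum(co$observable & !co_hit)
  list(
    summary = tibble::tibble(
      n_events = nrow(events),
      tp = sum(matched),
      fp = sum(!matched),
      n_observable = n_obs,
      missed = missed
    ),
    events = dplyr::mutate(events, matched = matched, origin = origin)
  )
}
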