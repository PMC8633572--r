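#' Crossover caller configuration
#'
#' @param confirm_window Number of retained markers after a state switch
#'   that must all carry the new state for the switch to be validated
#'   (the switch marker itself must carry it too, so the minimum validated
#'   run is `confirm_window + 1` retained markers). `0` disables validation:
#'   every allele change between consecutive retained markers is scored.
#' @param terminal_policy What to do with a switch closer than
#'   `confirm_window` retained markers to the chromosome end:
#'   `"require_all_remaining"` validates it when every remaining marker
#'   (at least one) carries the new state; `"reject"` never validates it.
#' @return A list of class `co_caller_config`.
#' @export
co_caller_config <- function(confirm_window = 3L,
                             terminal_policy = c("require_all_remaining",
                                                 "reject")) {
  confirm_window <- as.integer(confirm_window)
  if (is.na(confirm_window) || confirm_window < 0L) {
    abort("`confirm_window` must be a non-negative integer.")
  }
  structure(list(confirm_window = confirm_window,
                 terminal_policy = match.arg(terminal_policy)),
            class = "co_caller_config")
}

# Core scanner over one individual's retained (informative, non-missing)
# calls on one chromosome. Returns parallel integer vectors indexing the
# retained calls: left = last old-state marker, right = switch marker.
scan_state_switches <- function(calls, confirm_window, terminal_policy) {
  n <- length(calls)
  left <- integer(0); right <- integer(0); mult <- integer(0)
  if (n < 2L) {
    return(list(left = left, right = right, mult = mult))
  }
  state <- calls[1L]
  state_end <- 1L
  i <- 2L
  while (i <= n) {
    x <- calls[i]
    if (x == state) {
      state_end <- i
      i <- i + 1L
      next
    }
    n_after <- n - i
    validated <- if (n_after >= confirm_window) {
      confirm_window == 0L ||
        all(calls[(i + 1L):(i + confirm_window)] == x)
    } else if (terminal_policy == "require_all_remaining") {
      n_after >= 1L && all(calls[(i + 1L):n] == x)
    } else {
      FALSE
    }
    if (validated) {
      left <- c(left, state_end)
      right <- c(right, i)
      mult <- c(mult, if (x != "H" && state != "H") 2L else 1L)
      state <- x
      state_end <- i
    }
    i <- i + 1L
  }
  list(left = left, right = right, mult = mult)
}

#' Detect crossovers in a single call vector
#'
#' Scans one individual's ordered calls along one chromosome. Missing calls
#' are skipped transparently (they neither confirm nor break a state), so a
#' validated switch across skipped markers yields an event whose interval
#' spans them. A state switch is validated when the new call is maintained
#' over the following `confirm_window` retained markers; an unvalidated
#' (short) discordant run is treated as a likely miscall and masked, and
#' scanning resumes from the prior state. A validated switch between the two
#' opposite homozygous states counts as a double crossover
#' (multiplicity 2); any switch involving the heterozygous state counts one.
#'
#' @param calls Character vector of `A`/`H`/`B`/`NA` calls in map order.
#' @param marker_ids Marker ids parallel to `calls` (defaults to index).
#' @param positions_bp Physical positions parallel to `calls` (optional;
#'   when supplied the events carry `left_bp`, `right_bp`, `midpoint_bp`).
#' @param config A [co_caller_config()].
#' @return Tibble of events: `left_marker`, `right_marker`, `multiplicity`
#'   and, with positions, the physical interval and its midpoint (integer
#'   floor of the mean of the flanking positions).
#' @export
scan_crossovers <- function(calls, marker_ids = NULL, positions_bp = NULL,
                            config = co_caller_config()) {
  if (is.null(marker_ids)) marker_ids <- as.character(seq_along(calls))
  retained <- which(!is.na(calls) & calls != "NA")
  if (length(retained) < 2L) {
    if (length(retained) < 2L && length(calls) > 0L) {
      warn("Fewer than 2 retained markers; no crossovers can be scored.")
    }
    return(empty_events(!is.null(positions_bp)))
  }
  sw <- scan_state_switches(calls[retained], config$confirm_window,
                            config$terminal_policy)
  li <- retained[sw$left]
  ri <- retained[sw$right]
  out <- tibble::tibble(
    left_marker = marker_ids[li],
    right_marker = marker_ids[ri],
    multiplicity = sw$mult
  )
  if (!is.null(positions_bp)) {
    out$left_bp <- positions_bp[li]
    out$right_bp <- positions_bp[ri]
    out$midpoint_bp <- floor((out$left_bp + out$right_bp) / 2)
  }
  out
}

empty_events <- function(with_pos = TRUE) {
  out <- tibble::tibble(left_marker = character(), right_marker = character(),
                        multiplicity = integer())
  if (with_pos) {
    out$left_bp <- numeric(); out$right_bp <- numeric()
    out$midpoint_bp <- numeric()
  }
  out
}

#' Build per-family informative-marker masks
#'
#' A marker is informative for an F3 family only when it is heterozygous in
#' the family's parental F2, so that the F2 meiosis segregates there. When
#' the parental F2 genotypes are available the mask is simply the set of
#' markers called `H`; otherwise the mask is inferred from the family's F3
#' genotypes as the markers showing at least two distinct non-missing calls.
#' Families with fewer than two F3 individuals are skipped under inference,
#' with a warning.
#'
#' @param genotypes F3 genotype tibble (used for family membership, and for
#'   inference when `f2_genotypes` is `NULL`).
#' @param f2_genotypes Optional tibble of parental F2 genotypes with
#'   `family_id` (or `individual_id` equal to the family id) and one column
#'   per marker.
#' @return Tidy tibble (`family_id`, `marker_id`) listing each family's
#'   informative markers.
#' @export
build_family_masks <- function(genotypes, f2_genotypes = NULL) {
  assert_genotypes(genotypes)
  if (!is.null(f2_genotypes)) {
    if (!"family_id" %in% names(f2_genotypes)) {
      f2_genotypes <- dplyr::rename(f2_genotypes,
                                    family_id = "individual_id")
    }
    mk <- setdiff(names(f2_genotypes), geno_meta_cols)
    mat <- as.matrix(f2_genotypes[mk])
    hits <- which(!is.na(mat) & mat == "H", arr.ind = TRUE)
    return(tibble::tibble(
      family_id = f2_genotypes$family_id[hits[, 1]],
      marker_id = mk[hits[, 2]]
    ) |> dplyr::arrange(.data$family_id, .data$marker_id))
  }
  mk <- marker_cols(genotypes)
  mat <- geno_matrix(genotypes)
  fams <- split(seq_len(nrow(mat)), genotypes$family_id)
  res <- lapply(names(fams), function(f) {
    rows <- fams[[f]]
    if (length(rows) < 2L) {
      warn(paste0("Family ", f, " has fewer than 2 F3 individuals; ",
                  "skipped when inferring informative markers."))
      return(NULL)
    }
    sub <- mat[rows, , drop = FALSE]
    n_distinct <- apply(sub, 2, function(col) length(unique(col[!is.na(col)])))
    tibble::tibble(family_id = f, marker_id = mk[n_distinct >= 2L])
  })
  dplyr::bind_rows(res)
}

#' Detect crossovers in a population
#'
#' Applies [scan_crossovers()] per individual and chromosome, after
#' restricting each individual's calls to the markers informative for its
#' family (see [build_family_masks()]). Only recombination from the F2
#' meioses is scored this way: markers homozygous in the parental F2 carry
#' no signal and are excluded before scanning, not treated as breaks.
#'
#' @param genotypes Genotype tibble (`individual_id`, `family_id`,
#'   `population`, marker columns).
#' @param marker_map Marker map covering the genotype markers.
#' @param masks Tidy mask tibble from [build_family_masks()], or `NULL` to
#'   treat every marker as informative (used e.g. for the preliminary QC
#'   screen of hyper-recombinant individuals).
#' @param config A [co_caller_config()].
#' @return Tibble of crossover events with individual metadata, flanking
#'   markers, physical interval, midpoint and multiplicity.
#' @export
call_crossovers <- function(genotypes, marker_map, masks = NULL,
                            config = co_caller_config()) {
  assert_genotypes(genotypes)
  mm <- map_for_genotypes(marker_map, genotypes) |>
    dplyr::arrange(.data$chrom, .data$pos_bp)
  mat <- geno_matrix(genotypes)[, mm$marker_id, drop = FALSE]
  by_chrom <- split(seq_len(nrow(mm)), mm$chrom)

  mask_lookup <- NULL
  if (!is.null(masks)) {
    mask_lookup <- lapply(split(masks$marker_id, masks$family_id), as.character)
  }
  has_family <- "family_id" %in% names(genotypes)

  res <- vector("list", nrow(mat) * length(by_chrom))
  k <- 0L
  for (i in seq_len(nrow(mat))) {
    fam <- if (has_family) genotypes$family_id[i] else NA_character_
    informative <- rep(TRUE, nrow(mm))
    if (!is.null(mask_lookup)) {
      informative <- mm$marker_id %in% mask_lookup[[fam]]
    }
    for (chr in names(by_chrom)) {
      idx <- by_chrom[[chr]][informative[by_chrom[[chr]]]]
      if (length(idx) < 2L) next
      ev <- suppressWarnings(scan_crossovers(
        mat[i, idx], mm$marker_id[idx], mm$pos_bp[idx], config
      ))
      if (nrow(ev) == 0L) next
      ev$individual_id <- genotypes$individual_id[i]
      ev$family_id <- fam
      ev$population <- if ("population" %in% names(genotypes)) {
        genotypes$population[i]
      } else NA_character_
      ev$chrom <- chr
      k <- k + 1L
      res[[k]] <- ev
    }
  }
  cols <- c("individual_id", "family_id", "population", "chrom",
            "left_marker", "right_marker", "left_bp", "right_bp",
            "midpoint_bp", "multiplicity")
  if (k == 0L) {
    out <- empty_events(TRUE)
    out$individual_id <- character(); out$family_id <- character()
    out$population <- character(); out$chrom <- character()
    return(out[cols])
  }
  dplyr::bind_rows(res[seq_len(k)])[cols]
}

#' Remove family-shared double-crossover artifacts
#'
#' A crossover in the same physical interval in both gametes of the F1
#' swaps the phase of the resulting F2's haplotypes: downstream of it, every
#' homozygous F3 of that family shows the same validated hom-to-hom
#' (multiplicity 2) switch between the same flanking markers, mimicking a
#' burst of double crossovers that did not happen in the F2 meioses the
#' analysis is meant to score. Independent F2-meiosis double crossovers are
#' private to single individuals, so a multiplicity-2 event recurring at
#' identical flanks in several members of one family is diagnostic of a
#' parental phase change. This filter drops those recurrent doubles — the
#' programmatic analog of curating such artifacts by hand.
#'
#' @param events Event tibble from [call_crossovers()].
#' @param min_members Minimum number of family members sharing the same
#'   multiplicity-2 flanking pair for the group to be treated as a phase
#'   change and removed.
#' @return List with `events` (filtered) and `removed` (the dropped rows).
#' @export
filter_shared_doubles <- function(events, min_members = 3) {
  if (nrow(events) == 0) {
    return(list(events = events, removed = events))
  }
  flagged <- events |>
    dplyr::group_by(.data$family_id, .data$chrom, .data$left_marker,
                    .data$right_marker) |>
    dplyr::mutate(.shared = .data$multiplicity == 2L &
                    sum(.data$multiplicity == 2L) >= min_members) |>
    dplyr::ungroup()
  list(events = dplyr::filter(flagged, !.data$.shared) |>
         dplyr::select(-".shared"),
       removed = dplyr::filter(flagged, .data$.shared) |>
         dplyr::select(-".shared"))
}

#' Per-individual crossover counts
#'
#' Sums event multiplicities per individual (a double crossover counts 2).
#' Individuals of `genotypes` without any event are included with count 0.
#'
#' @param events Event tibble from [call_crossovers()].
#' @param genotypes Optional genotype tibble used to add zero-count rows.
#' @return Tibble (`individual_id`, `n_co`).
#' @export
count_crossovers <- function(events, genotypes = NULL) {
  counts <- events |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(n_co = sum(.data$multiplicity), .groups = "drop")
  if (!is.null(genotypes)) {
    counts <- tibble::tibble(individual_id = genotypes$individual_id) |>
      dplyr::left_join(counts, by = "individual_id") |>
      dplyr::mutate(n_co = dplyr::coalesce(.data$n_co, 0L))
  }
  counts
}
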