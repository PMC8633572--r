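#' Read a marker map
#'
#' Reads a delimited text file of marker coordinates and returns a tibble
#' sorted by chromosome and physical position. Column names are matched
#' loosely: the marker id column may be called `marker_id`, `marker` or `id`;
#' the chromosome column `chrom`, `chromosome` or `chr`; the position column
#' `pos_bp`, `position_bp`, `pos` or `position`; an optional zone column is
#' kept when present.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp` (integer
#'   base pairs) and, when present in the file, `zone`, sorted by
#'   chromosome then position.
#' @export
read_marker_map <- function(path, delim = NULL) {
  raw <- read_table_file(path, delim)
  nm <- names(raw)
  id_col <- match_col(nm, c("marker_id", "marker", "id"), "marker id", path)
  ch_col <- match_col(nm, c("chrom", "chromosome", "chr"), "chromosome", path)
  ps_col <- match_col(nm, c("pos_bp", "position_bp", "pos", "position"),
                      "position", path)
  pos_chr <- as.character(raw[[ps_col]])
  pos <- suppressWarnings(as.numeric(pos_chr))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 0)
  if (length(bad)) {
    abort(paste0("Non-integer position at data row ", bad[1], " ('",
                 pos_chr[bad[1]], "') in ", path))
  }
  out <- tibble::tibble(
    marker_id = as.character(raw[[id_col]]),
    chrom = as.character(raw[[ch_col]]),
    pos_bp = as.integer(pos)
  )
  zone_col <- intersect(c("zone"), nm)
  if (length(zone_col)) out$zone <- as.integer(raw[[zone_col]])
  assert_marker_map(out)
  dplyr::arrange(out, .data$chrom, .data$pos_bp)
}

#' Write a marker map
#'
#' @param marker_map Tibble as returned by [read_marker_map()].
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(marker_map, path) {
  assert_marker_map(marker_map)
  readr::write_tsv(marker_map, path)
  invisible(path)
}

#' Read a pedigree table
#'
#' @param path Delimited file with columns `individual_id`, `family_id`,
#'   `population` (each F3 individual assigned to its parental F2 family,
#'   each family to one genotype class).
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return Tibble with those three character columns.
#' @export
read_pedigree <- function(path, delim = NULL) {
  raw <- read_table_file(path, delim)
  need <- c("individual_id", "family_id", "population")
  if (!all(need %in% names(raw))) {
    abort(paste0("Pedigree file must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  ped <- tibble::as_tibble(lapply(raw[need], as.character))
  fam_pop <- dplyr::distinct(ped, .data$family_id, .data$population)
  dup <- fam_pop$family_id[duplicated(fam_pop$family_id)]
  if (length(dup)) {
    abort(paste0("Family assigned to more than one population: ",
                 paste(unique(dup), collapse = ", ")))
  }
  ped
}

#' Read a genotype table
#'
#' Reads A/H/B genotype calls (individuals as rows, markers as columns, or
#' transposed), aligns the marker columns to marker-map order, and joins the
#' pedigree metadata.
#'
#' @param path Delimited text file; first column individual ids, remaining
#'   columns markers (set `transposed = TRUE` for markers as rows).
#' @param marker_map Marker map tibble; genotype markers must be a subset of
#'   its ids.
#' @param pedigree Pedigree tibble from [read_pedigree()], or a path to one.
#' @param missing_tokens Call symbols treated as missing.
#' @param transposed Set `TRUE` when the file stores markers as rows.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return A genotype tibble: `individual_id`, `family_id`, `population`,
#'   then one character column per marker in map order with calls in
#'   `A`/`H`/`B`/`NA`.
#' @export
read_genotype_table <- function(path, marker_map, pedigree,
                                missing_tokens = c("NA", "N", "-", ""),
                                transposed = FALSE, delim = NULL) {
  assert_marker_map(marker_map)
  if (is.character(pedigree) && length(pedigree) == 1) {
    pedigree <- read_pedigree(pedigree)
  }
  raw <- read_table_file(path, delim, na = character())
  if (transposed) {
    ids <- names(raw)[-1]
    mk <- as.character(raw[[1]])
    mat <- t(as.matrix(raw[-1]))
    colnames(mat) <- mk
    raw <- dplyr::bind_cols(tibble::tibble(individual_id = ids),
                            tibble::as_tibble(mat))
  } else {
    names(raw)[1] <- "individual_id"
    raw$individual_id <- as.character(raw$individual_id)
  }
  mk <- setdiff(names(raw), "individual_id")
  unknown <- setdiff(mk, marker_map$marker_id)
  if (length(unknown)) {
    abort(paste0("Genotype marker(s) not in marker map: ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  calls <- as.matrix(raw[mk])
  storage.mode(calls) <- "character"
  calls[calls %in% missing_tokens | is.na(calls)] <- NA_character_
  bad <- setdiff(unique(as.vector(calls)), c("A", "H", "B", NA))
  if (length(bad)) {
    abort(paste0("Unknown call symbol(s): ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 ". Allowed: A, H, B and missing tokens ",
                 paste(shQuote(missing_tokens), collapse = ", ")))
  }
  no_ped <- setdiff(raw$individual_id, pedigree$individual_id)
  if (length(no_ped)) {
    abort(paste0("Individual(s) missing from pedigree: ",
                 paste(utils::head(no_ped, 5), collapse = ", ")))
  }
  # align columns to map order
  ord <- marker_map$marker_id[marker_map$marker_id %in% mk]
  out <- tibble::tibble(individual_id = raw$individual_id) |>
    dplyr::left_join(pedigree, by = "individual_id") |>
    dplyr::bind_cols(tibble::as_tibble(calls[, ord, drop = FALSE]))
  assert_genotypes(out)
}

#' Write a genotype table
#'
#' Writes calls as tab-delimited text with missing calls emitted as `NA`.
#'
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "NA")
  invisible(path)
}

#' Read a zone scheme
#'
#' Reads a BED-like table (`chrom`, `start_bp`, `end_bp`, `zone`) assigning
#' chromosome segments to the distal (1), interstitial (2) and
#' pericentromeric (3) compartments. Segments must tile each chromosome
#' from 0 without gaps or overlaps.
#'
#' @param path Delimited file with a header.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return Tibble with the four columns, sorted by chromosome and start.
#' @export
read_zone_scheme <- function(path, delim = NULL) {
  raw <- read_table_file(path, delim)
  need <- c("chrom", "start_bp", "end_bp", "zone")
  if (!all(need %in% names(raw))) {
    abort(paste0("Zone scheme must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  zs <- tibble::tibble(
    chrom = as.character(raw$chrom),
    start_bp = as.numeric(raw$start_bp),
    end_bp = as.numeric(raw$end_bp),
    zone = as.integer(raw$zone)
  ) |>
    dplyr::arrange(.data$chrom, .data$start_bp)
  validate_zone_scheme(zs)
  zs
}

validate_zone_scheme <- function(zone_scheme) {
  if (!all(zone_scheme$zone %in% 1:3)) {
    abort("Zones must be 1, 2 or 3.")
  }
  by_chr <- split(zone_scheme, zone_scheme$chrom)
  for (zs in by_chr) {
    if (zs$start_bp[1] != 0 ||
        any(zs$start_bp[-1] != zs$end_bp[-nrow(zs)]) ||
        any(zs$end_bp <= zs$start_bp)) {
      abort(paste0("Zone segments must tile chromosome ", zs$chrom[1],
                   " from 0 without gaps or overlaps."))
    }
  }
  invisible(zone_scheme)
}

#' Read a fertility table
#'
#' @param path Delimited file with columns `individual_id`, `population`,
#'   `fertile_seeds`, `total_florets` (one row per scored ear).
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return Tibble with those columns.
#' @export
read_fertility_table <- function(path, delim = NULL) {
  raw <- read_table_file(path, delim)
  need <- c("individual_id", "population", "fertile_seeds", "total_florets")
  if (!all(need %in% names(raw))) {
    abort(paste0("Fertility table must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  out <- tibble::tibble(
    individual_id = as.character(raw$individual_id),
    population = as.character(raw$population),
    fertile_seeds = as.integer(raw$fertile_seeds),
    total_florets = as.integer(raw$total_florets)
  )
  if (any(out$total_florets < 1) ||
      any(out$fertile_seeds < 0 | out$fertile_seeds > out$total_florets)) {
    abort("Need 0 <= fertile_seeds <= total_florets and total_florets >= 1.")
  }
  out
}

#' Write and read crossover event reports
#'
#' One row per detected event: individual, chromosome, flanking markers,
#' physical interval, midpoint and multiplicity. Output is tab-delimited and
#' bit-stable across runs on identical input.
#'
#' @param events Event tibble from [call_crossovers()].
#' @param path File path.
#' @return `path` (write) or the event tibble (read).
#' @export
write_co_report <- function(events, path) {
  cols <- c("individual_id", "family_id", "population", "chrom",
            "left_marker", "right_marker", "left_bp", "right_bp",
            "midpoint_bp", "multiplicity")
  keep <- intersect(cols, names(events))
  readr::write_tsv(events[keep], path)
  invisible(path)
}

#' @rdname write_co_report
#' @export
read_co_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    left_bp = readr::col_double(),
                    right_bp = readr::col_double(),
                    midpoint_bp = readr::col_double(),
                    multiplicity = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}

#' Write a recombination map report
#'
#' Writes the per-interval table (recombination fraction and Kosambi cM) of
#' a fitted map as tab-delimited text.
#'
#' @param rec_map A `xomap_map` object from [map_lengths()], or an interval
#'   tibble from [interval_recombination_fractions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_report <- function(rec_map, path) {
  intervals <- if (inherits(rec_map, "xomap_map")) rec_map$intervals else rec_map
  readr::write_tsv(intervals, path)
  invisible(path)
}

# -- helpers ------------------------------------------------------------

read_table_file <- function(path, delim = NULL, na = c("", "NA")) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = na, progress = FALSE)
}

match_col <- function(nm, candidates, what, path) {
  hit <- intersect(candidates, tolower(nm))
  if (!length(hit)) {
    abort(paste0("No ", what, " column (one of ",
                 paste(candidates, collapse = ", "), ") in ", path))
  }
  nm[match(hit[1], tolower(nm))]
}
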