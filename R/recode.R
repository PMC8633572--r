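#' Recode nucleotide calls to A/H/B
#'
#' Converts diploid nucleotide calls to the biparental A/H/B encoding given
#' the reference allele of each parent at every marker: `A` for the
#' parent-A homozygote, `B` for the parent-B homozygote, `H` for the
#' heterozygote carrying both parental alleles, and `NA` for anything else
#' (third alleles, or calls at markers where the parents share an allele).
#' Heterozygotes are unordered (`"CT"` is the same call as `"TC"`); a
#' single-letter call is taken as the corresponding homozygote.
#'
#' @param raw_calls Tibble with `individual_id` (plus optional `family_id`,
#'   `population`) and one character column of nucleotide calls per marker.
#' @param parent_a,parent_b Named character vectors of reference alleles
#'   (names are marker ids), or two-column data frames
#'   (`marker_id`, `allele`). Every marker of `raw_calls` must be present.
#' @param missing_tokens Call symbols treated as missing.
#' @return A list with `genotypes` (the A/H/B tibble; calls at unresolvable
#'   markers are `NA`) and `unresolvable` (ids of markers where the two
#'   parents carry the same allele). A warning reports calls that matched
#'   neither parental genotype.
#' @export
recode_nucleotides_to_abh <- function(raw_calls, parent_a, parent_b,
                                      missing_tokens = c("NA", "N", "-", "")) {
  parent_a <- as_allele_vector(parent_a, "parent_a")
  parent_b <- as_allele_vector(parent_b, "parent_b")
  mk <- marker_cols(raw_calls)
  absent <- setdiff(mk, intersect(names(parent_a), names(parent_b)))
  if (length(absent)) {
    abort(paste0("Marker(s) missing from parent reference: ",
                 paste(utils::head(absent, 5), collapse = ", ")))
  }
  a <- parent_a[mk]
  b <- parent_b[mk]
  unresolvable <- mk[a == b]

  mat <- as.matrix(raw_calls[mk])
  storage.mode(mat) <- "character"
  mat[mat %in% missing_tokens] <- NA_character_
  one <- !is.na(mat) & nchar(mat) == 1L
  mat[one] <- paste0(mat[one], mat[one])
  if (any(!is.na(mat) & nchar(mat) != 2L)) {
    abort("Raw calls must be one- or two-letter nucleotide strings.")
  }
  # unordered pair, alphabetical
  key <- matrix(norm_pair(mat), nrow = nrow(mat))

  hom_a <- matrix(rep(paste0(a, a), each = nrow(mat)), nrow = nrow(mat))
  hom_b <- matrix(rep(paste0(b, b), each = nrow(mat)), nrow = nrow(mat))
  het <- matrix(rep(norm_pair(paste0(a, b)), each = nrow(mat)),
                nrow = nrow(mat))
  out <- matrix(NA_character_, nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  out[!is.na(key) & key == hom_a] <- "A"
  out[!is.na(key) & key == hom_b] <- "B"
  out[!is.na(key) & key == het] <- "H"
  out[, mk %in% unresolvable] <- NA_character_

  n_bad <- sum(!is.na(key) & is.na(out) & !(col(key) %in% which(a == b)))
  if (n_bad > 0) {
    warn(paste0(n_bad, " call(s) matched neither parental genotype; ",
                "recoded as NA."))
  }
  genotypes <- dplyr::bind_cols(
    raw_calls[intersect(geno_meta_cols, names(raw_calls))],
    tibble::as_tibble(out)
  )
  list(genotypes = genotypes, unresolvable = unresolvable)
}

norm_pair <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  parts <- strsplit(toupper(x[ok]), "")
  out[ok] <- vapply(parts, function(p) paste(sort(p), collapse = ""), "")
  out
}

as_allele_vector <- function(x, arg) {
  if (is.data.frame(x)) {
    if (!all(c("marker_id", "allele") %in% names(x))) {
      abort(paste0("`", arg, "` data frame needs columns marker_id, allele."))
    }
    x <- setNames(toupper(as.character(x$allele)), x$marker_id)
  }
  if (is.null(names(x))) {
    abort(paste0("`", arg, "` must be named by marker id."))
  }
  toupper(x)
}
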