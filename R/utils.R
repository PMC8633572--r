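# Columns of a genotype tibble that are not marker calls.
geno_meta_cols <- c("individual_id", "family_id", "population")

marker_cols <- function(genotypes) {
  setdiff(names(genotypes), geno_meta_cols)
}

# Character matrix of calls (individuals x markers), NA for missing.
geno_matrix <- function(genotypes) {
  m <- as.matrix(genotypes[marker_cols(genotypes)])
  rownames(m) <- genotypes$individual_id
  storage.mode(m) <- "character"
  m
}

# Rebuild a genotype tibble from metadata and a call matrix.
geno_rebuild <- function(genotypes, mat) {
  meta <- genotypes[intersect(geno_meta_cols, names(genotypes))]
  dplyr::bind_cols(meta, tibble::as_tibble(mat))
}

assert_genotypes <- function(genotypes, call = rlang::caller_env()) {
  if (!is.data.frame(genotypes) || !"individual_id" %in% names(genotypes)) {
    abort("`genotypes` must be a data frame with an `individual_id` column.",
          call = call)
  }
  if (anyDuplicated(genotypes$individual_id)) {
    abort("`individual_id` values must be unique.", call = call)
  }
  bad <- setdiff(unique(unlist(genotypes[marker_cols(genotypes)])),
                 c("A", "H", "B", NA))
  if (length(bad)) {
    abort(paste0("Genotype calls must be A/H/B/NA; found: ",
                 paste(utils::head(bad, 5), collapse = ", ")), call = call)
  }
  invisible(genotypes)
}

assert_marker_map <- function(marker_map, call = rlang::caller_env()) {
  need <- c("marker_id", "chrom", "pos_bp")
  if (!is.data.frame(marker_map) || !all(need %in% names(marker_map))) {
    abort("`marker_map` needs columns marker_id, chrom, pos_bp.", call = call)
  }
  dup <- marker_map$marker_id[duplicated(marker_map$marker_id)]
  if (length(dup)) {
    abort(paste0("Duplicated marker id(s): ",
                 paste(unique(dup), collapse = ", ")), call = call)
  }
  invisible(marker_map)
}

# Align a marker map to the markers present in a genotype table, keeping
# map order (chromosome, then position).
map_for_genotypes <- function(marker_map, genotypes) {
  mk <- marker_cols(genotypes)
  missing <- setdiff(mk, marker_map$marker_id)
  if (length(missing)) {
    abort(paste0("Genotype marker(s) absent from marker map: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  dplyr::filter(marker_map, .data$marker_id %in% mk)
}
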