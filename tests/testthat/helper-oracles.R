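# Independent oracles and fixture builders, deliberately implemented with
# different algorithms than the package so that agreement is informative.

# Run-length-compression crossover oracle: compress the retained calls into
# maximal runs; the first run defines the starting state; a later run equal
# to the current state always extends it; a differing run becomes a new
# state when it is long enough (confirm_window + 1), or when it reaches the
# chromosome end with at least one confirming marker (terminal leniency);
# all other runs are masked as noise. Events sit between the last marker
# seen in the old state and the first marker of the new state's run.
oracle_scan <- function(calls, confirm_window = 3L,
                        terminal_policy = "require_all_remaining") {
  keep <- which(!is.na(calls))
  x <- calls[keep]
  empty <- data.frame(left = integer(0), right = integer(0),
                      mult = integer(0))
  if (length(x) < 2L) return(empty)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(x)
  state <- r$values[1L]
  state_end <- ends[1L]
  out <- empty
  for (k in seq_along(r$values)[-1L]) {
    v <- r$values[k]
    len <- r$lengths[k]
    if (v == state) {
      state_end <- ends[k]
      next
    }
    terminal_ok <- ends[k] == n &&
      terminal_policy == "require_all_remaining" && len >= 2L
    if (len >= confirm_window + 1L || terminal_ok) {
      mult <- if (v != "H" && state != "H") 2L else 1L
      out <- rbind(out, data.frame(left = keep[state_end],
                                   right = keep[starts[k]], mult = mult))
      state <- v
      state_end <- ends[k]
    }
  }
  out
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Call matrix of a genotype tibble (test-side convenience).
geno_matrix_of <- function(genotypes) {
  as.matrix(genotypes[setdiff(names(genotypes),
                              c("individual_id", "family_id", "population"))])
}

# Random A/H/B/NA call vector.
random_calls <- function(n, p_na = 0.1) {
  calls <- sample(c("A", "H", "B"), n, replace = TRUE)
  calls[runif(n) < p_na] <- NA_character_
  calls
}

# Minimal marker map: one chromosome, equally spaced markers.
toy_map <- function(n, chrom = "chr1H", spacing = 1000L) {
  tibble::tibble(marker_id = paste0("m", seq_len(n)), chrom = chrom,
                 pos_bp = spacing * seq_len(n))
}

# Genotype tibble from a named list of call vectors.
toy_genotypes <- function(calls_list, map, family_id = NULL,
                          population = "all") {
  n <- length(calls_list)
  if (is.null(family_id)) family_id <- rep("fam1", n)
  mat <- do.call(rbind, calls_list)
  colnames(mat) <- map$marker_id
  dplyr::bind_cols(
    tibble::tibble(individual_id = names(calls_list),
                   family_id = family_id,
                   population = rep_len(population, n)),
    tibble::as_tibble(mat)
  )
}

# Small simulated dataset used by several tests.
small_sim <- function(seed = 42, n_families = 4, n_f3 = 8,
                      n_markers = 700, classes = c(WT = 1),
                      error_rate = 0, missing_rate = 0,
                      genetic_length_cm = 70, n_chrom = 3) {
  genome <- sim_genome(n_chrom = n_chrom, chrom_length_bp = 6e8,
                       genetic_length_cm = genetic_length_cm,
                       n_markers = n_markers)
  design <- sim_design(n_families = n_families, n_f3_per_family = n_f3,
                       class_scaling = classes, error_rate = error_rate,
                       missing_rate = missing_rate, seed = seed)
  simulate_pedigree(genome, design)
}
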