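#' Define a genome for simulation
#'
#' Sets up chromosomes (physical length in bp, per-gamete genetic length in
#' cM), a crossover density profile over relative position, and a marker
#' panel. The default profile mirrors the distally skewed recombination of
#' large-genome cereals: a fixed share of crossover density
#' (`distal_weight`) falls uniformly in the two distal segments jointly
#' covering `distal_frac` of the chromosome (the outer quarter of each
#' arm), the rest uniformly everywhere. The default per-gamete genetic
#' length of 70 cM per chromosome puts a wild-type-like seven-chromosome
#' genome near 980 cM on the per-individual scale the pipeline reports (an
#' F3 individual unites two meiotic products).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Physical length(s) in bp (recycled).
#' @param genetic_length_cm Per-gamete genetic length(s) in cM (recycled).
#' @param distal_weight Share of crossover density in the distal segments.
#' @param distal_frac Combined relative width of the two distal segments.
#' @param n_markers Total marker count, split across chromosomes
#'   proportionally to physical length.
#' @param marker_placement `"uniform"` spaces markers evenly;
#'   `"weighted"` concentrates them like the crossover density.
#' @return Object of class `sim_genome`: `chromosomes` tibble, `profile`
#'   list and `marker_map` tibble.
#' @export
sim_genome <- function(n_chrom = 7, chrom_length_bp = 6.5e8,
                       genetic_length_cm = 70,
                       distal_weight = 0.7, distal_frac = 0.25,
                       n_markers = 12000,
                       marker_placement = c("uniform", "weighted")) {
  marker_placement <- match.arg(marker_placement)
  stopifnot(distal_weight >= 0, distal_weight <= 1,
            distal_frac > 0, distal_frac < 1,
            all(genetic_length_cm >= 0), n_markers >= n_chrom)
  chromosomes <- tibble::tibble(
    chrom = sprintf("chr%dH", seq_len(n_chrom)),
    length_bp = rep_len(chrom_length_bp, n_chrom),
    genetic_length_cm = rep_len(genetic_length_cm, n_chrom)
  )
  profile <- list(distal_weight = distal_weight, distal_frac = distal_frac)
  per_chrom <- diff(round(cumsum(c(0, chromosomes$length_bp)) /
                            sum(chromosomes$length_bp) * n_markers))
  maps <- purrr::pmap(
    list(chromosomes$chrom, chromosomes$length_bp, per_chrom),
    function(chr, len, m) {
      q <- (seq_len(m) - 0.5) / m
      u <- if (marker_placement == "uniform") q else
        q_co_position(q, profile)
      tibble::tibble(chrom = chr, pos_bp = as.integer(round(u * len)))
    }
  )
  marker_map <- dplyr::bind_rows(maps) |>
    dplyr::arrange(.data$chrom, .data$pos_bp) |>
    dplyr::mutate(marker_id = sprintf("m%05d", dplyr::row_number()),
                  .before = 1)
  structure(list(chromosomes = chromosomes, profile = profile,
                 marker_map = marker_map),
            class = "sim_genome")
}

# Quantile function of the crossover density over relative position [0, 1].
q_co_position <- function(p, profile) {
  w <- profile$distal_weight
  f <- profile$distal_frac
  h <- f / 2
  s_d <- w / f + (1 - w)        # density in distal segments
  s_m <- 1 - w                  # density in the middle
  p1 <- s_d * h                 # CDF at h
  p2 <- p1 + s_m * (1 - f)      # CDF at 1 - h
  out <- numeric(length(p))
  lo <- p <= p1
  mid <- p > p1 & p <= p2
  hi <- p > p2
  out[lo] <- p[lo] / s_d
  out[mid] <- h + (p[mid] - p1) / s_m
  out[hi] <- 1 - h + (p[hi] - p2) / s_d
  out
}

# Draw n crossover positions (bp) from the density profile.
r_co_positions <- function(n, length_bp, profile) {
  if (n == 0L) return(numeric(0))
  sort(q_co_position(runif(n), profile) * length_bp)
}

#' Simulation design
#'
#' Study layout and noise model for [simulate_pedigree()]: families per
#' genotype class, F3 plants per family, per-class scaling of the genetic
#' length (the genotypic signature of anti-crossover and pro-crossover
#' mutants), genotyping error and missingness. The default class scalings
#' follow the wild-type-relative map-length ratios of the four F3
#' populations the pipeline is designed around (a *recql4*-like class at
#' 1.95x, an *mlh3*-like class at 0.37x, their double at 1.71x).
#'
#' @param n_families F2 families per class.
#' @param n_f3_per_family F3 individuals genotyped per family.
#' @param class_scaling Named numeric vector: genetic-length multiplier per
#'   population class, applied to the F2 meioses.
#' @param obligate_co Force at least one crossover per chromosome per
#'   gamete. Off by default: the floor breaks the proportionality between
#'   a class's scaling factor and its realized crossover rate, which is the
#'   signature the classes exist to carry (see the methods vignette).
#' @param error_rate Per-call miscall probability (homozygote to
#'   heterozygote dominant mode; homozygote to opposite homozygote occurs
#'   at a tenth of this rate).
#' @param missing_rate Per-call missing probability.
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(n_families = 10, n_f3_per_family = 10,
                       class_scaling = c(WT = 1, recql4 = 1.95,
                                         mlh3 = 0.37, double = 1.71),
                       obligate_co = FALSE,
                       error_rate = 0.001, missing_rate = 0.02,
                       seed = NULL) {
  stopifnot(n_families >= 1, n_f3_per_family >= 1,
            all(class_scaling > 0), !is.null(names(class_scaling)),
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_families = as.integer(n_families),
                 n_f3_per_family = as.integer(n_f3_per_family),
                 class_scaling = class_scaling,
                 obligate_co = isTRUE(obligate_co),
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_design")
}

#' Simulate one meiotic product
#'
#' Draws a crossover count from Poisson(genetic length / 100), optionally
#' raised to 1 when zero (obligate crossover), places the crossovers
#' independently along the chromosome according to the density profile (no
#' interference), picks the starting parental haplotype by a fair coin, and
#' returns the recombinant haplotype read off at the marker positions.
#'
#' @param hap1,hap2 Parental haplotypes: equal-length vectors of allele
#'   codes at the marker positions.
#' @param marker_pos_bp Marker positions on the chromosome.
#' @param length_bp Chromosome physical length.
#' @param genetic_length_cm Per-gamete genetic length in cM (Poisson mean
#'   is this divided by 100).
#' @param profile Density profile list (`distal_weight`, `distal_frac`).
#' @param obligate_co Force at least one crossover.
#' @return List with `alleles` (the gamete at the marker positions) and
#'   `co_pos_bp` (sorted crossover positions).
#' @export
simulate_gamete <- function(hap1, hap2, marker_pos_bp, length_bp,
                            genetic_length_cm,
                            profile = list(distal_weight = 0.7,
                                           distal_frac = 0.25),
                            obligate_co = FALSE) {
  stopifnot(length(hap1) == length(hap2),
            length(hap1) == length(marker_pos_bp))
  k <- rpois(1L, genetic_length_cm / 100)
  if (obligate_co && k == 0L) k <- 1L
  co <- r_co_positions(k, length_bp, profile)
  start <- rbinom(1L, 1L, 0.5)
  origin <- (start + findInterval(marker_pos_bp, co)) %% 2L
  alleles <- ifelse(origin == 0L, hap1, hap2)
  list(alleles = alleles, co_pos_bp = co)
}

#' Simulate an F1 -> F2 -> F3 selfing pedigree
#'
#' Forward simulation of the genetic design the pipeline analyses: a fully
#' heterozygous F1 is selfed, each F2 is the union of two independent F1
#' meiotic products, and each F3 the union of two independent F2 meiotic
#' products. Crossovers in the F2 meioses are observable in the F3
#' genotypes only where the parental F2 is heterozygous; the simulator
#' records every true crossover, each F2's informative-marker set, and the
#' rare phase flips (a crossover in the same marker interval in both F1
#' gametes) that mimic double crossovers family-wide. F1 meioses occur at
#' the base genetic length; F2 meioses are scaled per class. Genotypes are
#' returned clean; add genotyping error and missingness with
#' [inject_noise()].
#'
#' @param genome A [sim_genome()].
#' @param design A [sim_design()].
#' @return List of class `xomap_sim`: `genotypes` (clean F3 calls),
#'   `pedigree`, `f2_genotypes`, `marker_map`, `zone_scheme`, `truth`
#'   (class `xomap_truth`: `co`, `f2_informative`, `phase_flips`,
#'   `n_meioses`), `genome`, `design`.
#' @export
simulate_pedigree <- function(genome, design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  mm <- genome$marker_map
  chroms <- genome$chromosomes
  idx_by_chrom <- lapply(chroms$chrom,
                         function(ch) which(mm$chrom == ch))
  names(idx_by_chrom) <- chroms$chrom
  classes <- names(design$class_scaling)
  n_f3_total <- length(classes) * design$n_families * design$n_f3_per_family
  n_fam_total <- length(classes) * design$n_families

  geno <- matrix(NA_character_, n_f3_total, nrow(mm),
                 dimnames = list(NULL, mm$marker_id))
  f2_geno <- matrix(NA_character_, n_fam_total, nrow(mm),
                    dimnames = list(NULL, mm$marker_id))
  ped <- vector("list", n_f3_total)
  f2_ids <- character(n_fam_total)
  co_rec <- list()
  inf_rec <- list()
  flip_rec <- list()
  row_f3 <- 0L
  row_f2 <- 0L

  for (cl in classes) {
    scale <- design$class_scaling[[cl]]
    for (f in seq_len(design$n_families)) {
      fam_id <- sprintf("%s_f%02d", cl, f)
      row_f2 <- row_f2 + 1L
      f2_ids[row_f2] <- fam_id
      f2_hap <- vector("list", nrow(chroms))
      for (c_i in seq_len(nrow(chroms))) {
        idx <- idx_by_chrom[[chroms$chrom[c_i]]]
        pos <- mm$pos_bp[idx]
        zero <- rep(0L, length(idx))
        one <- rep(1L, length(idx))
        # two F1 meiotic products at the base rate
        g1 <- simulate_gamete(zero, one, pos, chroms$length_bp[c_i],
                              chroms$genetic_length_cm[c_i],
                              genome$profile, design$obligate_co)
        g2 <- simulate_gamete(zero, one, pos, chroms$length_bp[c_i],
                              chroms$genetic_length_cm[c_i],
                              genome$profile, design$obligate_co)
        f2_hap[[c_i]] <- list(h1 = g1$alleles, h2 = g2$alleles)
        f2_geno[row_f2, idx] <- c("A", "H", "B")[g1$alleles +
                                                   g2$alleles + 1L]
        het <- g1$alleles != g2$alleles
        inf_rec[[length(inf_rec) + 1L]] <- tibble::tibble(
          family_id = fam_id, marker_id = mm$marker_id[idx][het]
        )
        # phase flips: both haplotypes change between adjacent het markers
        if (sum(het) >= 2L) {
          hp <- which(het)
          adj <- hp[-length(hp)]
          nxt <- hp[-1L]
          flip <- g1$alleles[adj] != g1$alleles[nxt]
          if (any(flip)) {
            flip_rec[[length(flip_rec) + 1L]] <- tibble::tibble(
              family_id = fam_id, chrom = chroms$chrom[c_i],
              left_bp = pos[adj[flip]], right_bp = pos[nxt[flip]]
            )
          }
        }
      }
      for (j in seq_len(design$n_f3_per_family)) {
        row_f3 <- row_f3 + 1L
        ind_id <- sprintf("%s_p%02d", fam_id, j)
        ped[[row_f3]] <- tibble::tibble(individual_id = ind_id,
                                        family_id = fam_id,
                                        population = cl)
        for (c_i in seq_len(nrow(chroms))) {
          idx <- idx_by_chrom[[chroms$chrom[c_i]]]
          pos <- mm$pos_bp[idx]
          hp <- f2_hap[[c_i]]
          len_cm <- chroms$genetic_length_cm[c_i] * scale
          for (gm in 1:2) {
            g <- simulate_gamete(hp$h1, hp$h2, pos,
                                 chroms$length_bp[c_i], len_cm,
                                 genome$profile, design$obligate_co)
            if (gm == 1L) {
              a1 <- g$alleles
            } else {
              a2 <- g$alleles
            }
            if (length(g$co_pos_bp)) {
              co_rec[[length(co_rec) + 1L]] <- tibble::tibble(
                individual_id = ind_id, family_id = fam_id,
                population = cl, chrom = chroms$chrom[c_i],
                gamete = gm, pos_bp = g$co_pos_bp
              )
            }
          }
          geno[row_f3, idx] <- c("A", "H", "B")[a1 + a2 + 1L]
        }
      }
    }
  }

  pedigree <- dplyr::bind_rows(ped)
  genotypes <- dplyr::bind_cols(pedigree, tibble::as_tibble(geno))
  f2_genotypes <- dplyr::bind_cols(tibble::tibble(family_id = f2_ids),
                                   tibble::as_tibble(f2_geno))
  f2_informative <- dplyr::bind_rows(inf_rec)
  co <- if (length(co_rec)) dplyr::bind_rows(co_rec) else
    tibble::tibble(individual_id = character(), family_id = character(),
                   population = character(), chrom = character(),
                   gamete = integer(), pos_bp = numeric())
  co <- flag_observable(co, f2_informative, mm)
  truth <- structure(
    list(co = co,
         f2_informative = f2_informative,
         phase_flips = if (length(flip_rec)) dplyr::bind_rows(flip_rec) else
           tibble::tibble(family_id = character(), chrom = character(),
                          left_bp = numeric(), right_bp = numeric()),
         n_meioses = 2L * n_f3_total),
    class = "xomap_truth")
  structure(list(genotypes = genotypes, pedigree = pedigree,
                 f2_genotypes = f2_genotypes, marker_map = mm,
                 zone_scheme = sim_zone_scheme(genome), truth = truth,
                 genome = genome, design = design),
            class = "xomap_sim")
}

# A true crossover is (potentially) observable when its family's parental
# F2 carries informative (heterozygous) markers on both sides of it.
flag_observable <- function(co, f2_informative, marker_map) {
  if (nrow(co) == 0L) {
    co$observable <- logical(0)
    return(co)
  }
  pos_lookup <- setNames(marker_map$pos_bp, marker_map$marker_id)
  chrom_lookup <- setNames(marker_map$chrom, marker_map$marker_id)
  inf <- f2_informative |>
    dplyr::mutate(pos_bp = pos_lookup[.data$marker_id],
                  chrom = chrom_lookup[.data$marker_id]) |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::summarise(lo = min(.data$pos_bp), hi = max(.data$pos_bp),
                     .groups = "drop")
  co |>
    dplyr::left_join(inf, by = c("family_id", "chrom")) |>
    dplyr::mutate(observable = !is.na(.data$lo) & .data$pos_bp > .data$lo &
                    .data$pos_bp < .data$hi) |>
    dplyr::select(-"lo", -"hi")
}

#' Zone scheme of a simulated genome
#'
#' Writes a symmetric three-zone scheme matching the simulator's density
#' profile: zone 1 covers the two distal segments (the outer
#' `distal_frac / 2` of each end), zone 3 the central 30% of the
#' chromosome, zone 2 the segments between.
#'
#' @param genome A [sim_genome()].
#' @param zone3_frac Relative width of the pericentromeric zone.
#' @return Zone scheme tibble (`chrom`, `start_bp`, `end_bp`, `zone`).
#' @export
sim_zone_scheme <- function(genome, zone3_frac = 0.30) {
  h <- genome$profile$distal_frac / 2
  z3 <- zone3_frac / 2
  stopifnot(h < 0.5 - z3)
  rel <- c(0, h, 0.5 - z3, 0.5 + z3, 1 - h, 1)
  zones <- c(1L, 2L, 3L, 2L, 1L)
  purrr::pmap(list(genome$chromosomes$chrom, genome$chromosomes$length_bp),
              function(chr, len) {
                tibble::tibble(chrom = chr,
                               start_bp = rel[-length(rel)] * len,
                               end_bp = rel[-1] * len,
                               zone = zones)
              }) |>
    dplyr::bind_rows()
}

#' Inject genotyping noise
#'
#' Adds the two artifact modes that plague array calls in practice:
#' isolated miscalls (dominantly homozygote-to-heterozygote, which is what
#' inflates naive crossover counts; heterozygotes miscall to a random
#' homozygote, and homozygotes flip to the opposite homozygote at a tenth
#' of the rate) and missing calls. Each call is perturbed independently.
#'
#' @param genotypes Clean genotype tibble.
#' @param error_rate Per-call miscall probability.
#' @param missing_rate Per-call missing probability.
#' @param seed Optional seed (same seed, same noise pattern).
#' @return List with `genotypes` (noisy) and `noise_log`, a tibble of
#'   perturbed calls (`individual_id`, `marker_id`, `original`, `observed`,
#'   `type`).
#' @export
inject_noise <- function(genotypes, error_rate = 0.001, missing_rate = 0.02,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- geno_matrix(genotypes)
  orig <- mat
  n <- length(mat)
  mis1 <- runif(n) < error_rate
  mis2 <- runif(n) < error_rate / 10
  gone <- runif(n) < missing_rate
  is_hom <- !is.na(orig) & (orig == "A" | orig == "B")
  is_het <- !is.na(orig) & orig == "H"
  mat[mis1 & is_hom] <- "H"
  k <- which(mis1 & is_het)
  if (length(k)) mat[k] <- sample(c("A", "B"), length(k), replace = TRUE)
  swap <- mis2 & is_hom & !mis1
  mat[swap] <- ifelse(orig[swap] == "A", "B", "A")
  mat[gone] <- NA_character_

  changed <- which((is.na(mat) != is.na(orig)) |
                     (!is.na(mat) & !is.na(orig) & mat != orig))
  rw <- ((changed - 1L) %% nrow(mat)) + 1L
  cl <- ((changed - 1L) %/% nrow(mat)) + 1L
  noise_log <- tibble::tibble(
    individual_id = genotypes$individual_id[rw],
    marker_id = colnames(mat)[cl],
    original = orig[changed],
    observed = mat[changed],
    type = ifelse(is.na(mat[changed]), "missing", "miscall")
  )
  list(genotypes = geno_rebuild(genotypes, mat), noise_log = noise_log)
}
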