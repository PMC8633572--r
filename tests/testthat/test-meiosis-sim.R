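test_that("gamete simulation respects degenerate inputs", {
  pos <- seq(1e5, 1e6, by = 1e5)
  h1 <- rep(0L, 10); h2 <- rep(1L, 10)
  set.seed(1)
  g <- simulate_gamete(h1, h2, pos, 1e6, genetic_length_cm = 0)
  expect_length(g$co_pos_bp, 0)
  expect_true(all(g$alleles == h1) || all(g$alleles == h2))

  # homozygous parent: gamete identical whatever the crossover count
  set.seed(2)
  hom <- simulate_gamete(h1, h1, pos, 1e6, genetic_length_cm = 500)
  expect_equal(hom$alleles, h1)
})

test_that("crossover counts are Poisson with the map-length mean", {
  set.seed(60)
  counts <- vapply(1:10000, function(i) {
    k <- length(simulate_gamete(0L, 1L, 5e5, 1e6, 100)$co_pos_bp)
    k
  }, numeric(1))
  expect_equal(mean(counts), 1.00, tolerance = 0.03)
  # obligate floor removes zeros
  set.seed(61)
  k0 <- vapply(1:200, function(i) {
    length(simulate_gamete(0L, 1L, 5e5, 1e6, 20,
                           obligate_co = TRUE)$co_pos_bp)
  }, numeric(1))
  expect_true(all(k0 >= 1))
})

test_that("crossover positions follow the distal density profile", {
  set.seed(62)
  prof <- list(distal_weight = 0.7, distal_frac = 0.25)
  pos <- replicate(4000, simulate_gamete(0L, 1L, 5e5, 1e6, 100,
                                         profile = prof)$co_pos_bp) |>
    unlist()
  distal <- mean(pos < 1.25e5 | pos > 8.75e5)
  expect_equal(distal, 0.7 + 0.3 * 0.25, tolerance = 0.03)
})

test_that("the pedigree carries Mendelian structure", {
  sim <- small_sim(seed = 63, n_families = 200, n_f3 = 1, n_markers = 300,
                   n_chrom = 2)
  f2 <- sim$f2_genotypes
  het <- rowMeans(as.matrix(f2[-1]) == "H")
  expect_lt(abs(mean(het) - 0.5), 0.02)

  # markers homozygous in the F2 parent are invariant within its family
  sim2 <- small_sim(seed = 64, n_families = 3, n_f3 = 8, n_markers = 300)
  f2m <- as.matrix(sim2$f2_genotypes[-1])
  rownames(f2m) <- sim2$f2_genotypes$family_id
  g <- geno <- sim2$genotypes
  for (f in rownames(f2m)) {
    fam_rows <- g[g$family_id == f, ]
    hom <- names(which(f2m[f, ] != "H"))
    sub <- as.matrix(fam_rows[hom])
    expect_true(all(apply(sub, 2, function(x) length(unique(x)) == 1)))
    # and the inherited call equals the F2's own call
    expect_true(all(sub[1, ] == f2m[f, hom]))
  }

  # allele frequency across many F2s is balanced at every marker
  f2a <- as.matrix(f2[-1])
  freq <- (2 * colSums(f2a == "A") + colSums(f2a == "H")) / (2 * nrow(f2a))
  expect_lt(abs(mean(freq) - 0.5), 0.02)
})

test_that("class scaling multiplies the true F2-meiosis crossover rate", {
  sim <- small_sim(seed = 65, n_families = 100, n_f3 = 10, n_markers = 140,
                   classes = c(base = 1, scaled = 1.95), n_chrom = 7,
                   genetic_length_cm = 70)
  co <- sim$truth$co
  ped <- sim$pedigree
  n_per_class <- table(ped$population) * 2  # two meioses per individual
  expect_true(all(n_per_class >= 400))
  rate <- tapply(rep(1, nrow(co)), co$population, sum) / n_per_class
  expect_lt(abs(unname(rate["scaled"] / rate["base"]) - 1.95), 0.05)
})

test_that("noise injection is binomial, biased to het, and reproducible", {
  sim <- small_sim(seed = 66, n_families = 5, n_f3 = 10, n_markers = 2000,
                   n_chrom = 2)
  clean <- sim$genotypes

  none <- inject_noise(clean, error_rate = 0, missing_rate = 0, seed = 1)
  expect_identical(none$genotypes, clean)
  expect_equal(nrow(none$noise_log), 0)

  noisy <- inject_noise(clean, error_rate = 0.01, missing_rate = 0,
                        seed = 67)
  n_calls <- nrow(clean) * length(setdiff(names(clean),
                                          c("individual_id", "family_id",
                                            "population")))
  expect_gte(n_calls, 1e5)
  n_mis <- sum(noisy$noise_log$type == "miscall")
  hom_frac <- mean(geno_matrix_of(clean) %in% c("A", "B"))
  expected <- n_calls * (0.01 + 0.001 * hom_frac * 0.99)
  expect_lt(abs(n_mis - expected), 60)
  # dominant mode: homozygote -> heterozygote
  hom_to_het <- with(noisy$noise_log[noisy$noise_log$type == "miscall", ],
                     mean(original %in% c("A", "B") & observed == "H"))
  expect_gt(hom_to_het, 0.5)

  again <- inject_noise(clean, error_rate = 0.01, missing_rate = 0,
                        seed = 67)
  expect_identical(noisy$genotypes, again$genotypes)
})

test_that("identical seed and design reproduce the simulation exactly", {
  a <- small_sim(seed = 68, n_families = 2, n_f3 = 4, n_markers = 200)
  b <- small_sim(seed = 68, n_families = 2, n_f3 = 4, n_markers = 200)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$co, b$truth$co)
})

test_that("truth matching classifies called events", {
  sim <- small_sim(seed = 69, n_families = 4, n_f3 = 8, n_markers = 700)
  masks <- build_family_masks(sim$genotypes, sim$f2_genotypes)
  ev <- call_crossovers(sim$genotypes, sim$marker_map, masks)
  tm <- truth_match(ev, sim$truth)
  expect_equal(tm$summary$fp, 0L)  # error-free data: nothing spurious
  expect_equal(tm$summary$tp, nrow(ev))
  expect_gte(tm$summary$missed, 0L)

  empty <- truth_match(ev[0, ], sim$truth)
  expect_equal(empty$summary$tp, 0L)
  expect_equal(empty$summary$missed, empty$summary$n_observable)
})
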