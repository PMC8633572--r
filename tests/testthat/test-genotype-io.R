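test_that("marker maps are sorted on read and round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchrom\tpos_bp",
               "m1\tchr1H\t100", "m2\tchr1H\t50", "m3\tchr2H\t10"), path)
  mm <- read_marker_map(path)
  expect_equal(mm$marker_id, c("m2", "m1", "m3"))
  expect_true(is.integer(mm$pos_bp))

  # large synthetic map round-trips identically
  set.seed(7)
  big <- tibble::tibble(
    marker_id = sprintf("m%05d", 1:11965),
    chrom = sort(sample(sprintf("chr%dH", 1:7), 11965, replace = TRUE)),
    pos_bp = NA_integer_
  ) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(pos_bp = sort(sample.int(6e8, dplyr::n()))) |>
    dplyr::ungroup() |>
    dplyr::arrange(chrom, pos_bp)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_marker_map(big, p2)
  expect_equal(read_marker_map(p2), big)
})

test_that("marker map errors name the offending record", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,chr,pos", "m1,chr1H,100", "m1,chr1H,200"), path)
  expect_error(read_marker_map(path), "m1")
  writeLines(c("id,chr,pos", "m1,chr1H,100", "m2,chr1H,2.5"), path)
  expect_error(read_marker_map(path), "row 2")
})

test_that("genotype tables align to map order regardless of column order", {
  mm <- toy_map(3)
  ped <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tfamily_id\tpopulation",
               "i1\tf1\tWT", "i2\tf1\tWT"), ped)
  g1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tm1\tm2\tm3",
               "i1\tA\tH\tB", "i2\tB\tNA\tA"), g1)
  tab <- read_genotype_table(g1, mm, read_pedigree(ped))
  expect_equal(unname(unlist(tab[1, c("m1", "m2", "m3")])), c("A", "H", "B"))
  expect_true(is.na(tab$m2[2]))

  # shuffled columns give the identical table
  g2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tm3\tm1\tm2",
               "i1\tB\tA\tH", "i2\tA\tB\tNA"), g2)
  expect_equal(read_genotype_table(g2, mm, read_pedigree(ped)), tab)

  # transposed layout too
  g3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\ti1\ti2", "m1\tA\tB", "m2\tH\tNA", "m3\tB\tA"), g3)
  expect_equal(read_genotype_table(g3, mm, read_pedigree(ped),
                                   transposed = TRUE), tab)
})

test_that("genotype reading rejects unknown markers, symbols and orphans", {
  mm <- toy_map(2)
  ped <- tibble::tibble(individual_id = "i1", family_id = "f1",
                        population = "WT")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tmX\tm2", "i1\tA\tB"), g)
  expect_error(read_genotype_table(g, mm, ped), "mX")
  writeLines(c("individual_id\tm1\tm2", "i1\tA\tZ"), g)
  expect_error(read_genotype_table(g, mm, ped), "Z")
  writeLines(c("individual_id\tm1\tm2", "i9\tA\tB"), g)
  expect_error(read_genotype_table(g, mm, ped), "i9")
})

test_that("nucleotide recoding covers all unordered diploid genotypes", {
  nt <- c("A", "C", "G", "T")
  pairs <- unique(apply(expand.grid(nt, nt), 1,
                        function(p) paste(sort(p), collapse = "")))
  expect_length(pairs, 10)
  raw <- dplyr::bind_cols(
    tibble::tibble(individual_id = paste0("i", seq_along(pairs))),
    tibble::as_tibble(matrix(pairs, ncol = 1, dimnames = list(NULL, "m1")))
  )
  res <- suppressWarnings(
    recode_nucleotides_to_abh(raw, c(m1 = "C"), c(m1 = "T"))
  )
  calls <- res$genotypes$m1
  expect_equal(calls[pairs == "CC"], "A")
  expect_equal(calls[pairs == "TT"], "B")
  expect_equal(calls[pairs == "CT"], "H")
  expect_equal(sum(!is.na(calls)), 3)

  # heterozygotes are unordered; warning logged for non-parental calls
  raw2 <- raw[1, ]
  raw2$m1 <- "TC"
  expect_equal(
    recode_nucleotides_to_abh(raw2, c(m1 = "C"), c(m1 = "T"))$genotypes$m1,
    "H")
  raw2$m1 <- "GG"
  expect_warning(
    res2 <- recode_nucleotides_to_abh(raw2, c(m1 = "C"), c(m1 = "T")),
    "neither parental")
  expect_true(is.na(res2$genotypes$m1))
})

test_that("recoding flags unresolvable markers and missing references", {
  raw <- tibble::tibble(individual_id = "i1", m1 = "CC", m2 = "AG")
  res <- recode_nucleotides_to_abh(raw, c(m1 = "C", m2 = "A"),
                                   c(m1 = "C", m2 = "G"))
  expect_equal(res$unresolvable, "m1")
  expect_true(is.na(res$genotypes$m1))
  expect_equal(res$genotypes$m2, "H")
  expect_error(recode_nucleotides_to_abh(raw, c(m1 = "C"), c(m1 = "T")),
               "m2")
})

test_that("crossover reports round-trip byte-identically", {
  mm <- toy_map(8)
  calls <- list(i1 = c("A", "A", "A", "A", "H", "H", "H", "H"))
  geno <- toy_genotypes(calls, mm)
  ev <- call_crossovers(geno, mm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$midpoint_bp, floor((4000 + 5000) / 2))

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_co_report(ev, p1)
  write_co_report(read_co_report(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  # empty event list gives a header-only file
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_co_report(ev[0, ], p3)
  expect_length(readLines(p3), 1)
})
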