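test_that("three-marker validation scores the canonical switch patterns", {
  mm <- toy_map(8)
  cfg <- co_caller_config()

  ev <- scan_crossovers(c("A", "A", "A", "A", "H", "H", "H", "H"),
                        mm$marker_id, mm$pos_bp, cfg)
  expect_equal(ev$left_marker, "m4")
  expect_equal(ev$right_marker, "m5")
  expect_equal(ev$multiplicity, 1L)

  # an isolated discordant call is masked, not scored
  expect_equal(nrow(scan_crossovers(c("A", "A", "A", "H", "A", "A", "A", "A"),
                                    mm$marker_id, mm$pos_bp, cfg)), 0)

  # direct hom-to-hom switch is a double crossover
  ev2 <- scan_crossovers(c("A", "A", "A", "A", "B", "B", "B", "B"),
                         mm$marker_id, mm$pos_bp, cfg)
  expect_equal(ev2$multiplicity, 2L)
  expect_equal(ev2$left_marker, "m4")

  # missing calls are skipped; the interval spans them
  mm9 <- toy_map(9)
  ev3 <- scan_crossovers(c("A", "A", "A", "A", NA, "H", "H", "H", "H"),
                         mm9$marker_id, mm9$pos_bp, cfg)
  expect_equal(c(ev3$left_marker, ev3$right_marker), c("m4", "m6"))
  expect_equal(ev3$midpoint_bp, floor((4000 + 6000) / 2))

  expect_equal(nrow(scan_crossovers(rep("H", 8), mm$marker_id,
                                    mm$pos_bp, cfg)), 0)

  expect_warning(scan_crossovers(c("A", NA, NA), config = cfg),
                 "Fewer than 2")
})

test_that("terminal switches follow the configured policy", {
  mm <- toy_map(6)
  lenient <- co_caller_config(terminal_policy = "require_all_remaining")
  strict <- co_caller_config(terminal_policy = "reject")
  calls <- c("A", "A", "A", "A", "H", "H")  # 1 confirming marker at the end
  expect_equal(nrow(scan_crossovers(calls, mm$marker_id, mm$pos_bp,
                                    lenient)), 1)
  expect_equal(nrow(scan_crossovers(calls, mm$marker_id, mm$pos_bp,
                                    strict)), 0)
  # a switch at the very last marker has no confirming marker: never scored
  last <- c("A", "A", "A", "A", "A", "H")
  expect_equal(nrow(scan_crossovers(last, mm$marker_id, mm$pos_bp,
                                    lenient)), 0)
})

test_that("caller agrees with the run-compression oracle on random vectors", {
  set.seed(101)
  for (rep in 1:400) {
    n <- sample(2:30, 1)
    calls <- random_calls(n)
    cw <- sample(0:4, 1)
    cfg <- co_caller_config(confirm_window = cw)
    got <- scan_crossovers(calls, config = cfg) |> suppressWarnings()
    want <- oracle_scan(calls, cw)
    expect_equal(as.integer(got$left_marker), want$left,
                 info = paste(calls, collapse = ","))
    expect_equal(as.integer(got$right_marker), want$right)
    expect_equal(got$multiplicity, want$mult)
  }
})

test_that("a wider confirmation window never adds events", {
  set.seed(202)
  for (rep in 1:100) {
    calls <- random_calls(sample(5:40, 1))
    counts <- vapply(0:5, function(cw) {
      suppressWarnings(nrow(scan_crossovers(
        calls, config = co_caller_config(confirm_window = cw))))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

# Random vector built from validated-length state runs, optionally with
# isolated miscalls sprinkled in.
random_blocks <- function(n_blocks, min_len = 4, max_len = 9,
                          n_miscalls = 0) {
  states <- character(n_blocks)
  states[1] <- sample(c("A", "H", "B"), 1)
  for (k in seq_len(n_blocks)[-1]) {
    states[k] <- sample(setdiff(c("A", "H", "B"), states[k - 1]), 1)
  }
  calls <- rep(states, times = sample(min_len:max_len, n_blocks,
                                      replace = TRUE))
  if (n_miscalls > 0) {
    at <- sample(5:(length(calls) - 4), n_miscalls)
    at <- at[!duplicated(at %/% 3)]  # keep miscalls isolated
    calls[at] <- vapply(calls[at], function(v) {
      sample(setdiff(c("A", "H", "B"), v), 1)
    }, "")
  }
  calls
}

test_that("clean state blocks give exactly mirrored events under reversal", {
  set.seed(303)
  cfg <- co_caller_config()
  for (rep in 1:60) {
    calls <- random_blocks(sample(3:6, 1))
    n <- length(calls)
    ids <- as.character(seq_len(n))
    fwd <- scan_crossovers(calls, ids, config = cfg)
    bwd <- scan_crossovers(rev(calls), rev(ids), config = cfg)
    expect_equal(fwd$left_marker, rev(bwd$right_marker))
    expect_equal(fwd$right_marker, rev(bwd$left_marker))
    expect_equal(fwd$multiplicity, rev(bwd$multiplicity))
  }
})

test_that("isolated miscalls leave interior event counts direction-free", {
  # an unvalidated run can shift an event's flanking markers within the
  # masked gap, but between two anchored chromosome ends it cannot create
  # or destroy a validated state, so event counts and multiplicities mirror
  set.seed(304)
  cfg <- co_caller_config()
  for (rep in 1:100) {
    blocks <- random_blocks(sample(4:7, 1))
    anchor1 <- rep(sample(setdiff(c("A", "H", "B"), blocks[1]), 1), 8)
    anchor2 <- rep(sample(setdiff(c("A", "H", "B"),
                                  blocks[length(blocks)]), 1), 8)
    calls <- c(anchor1, blocks, anchor2)
    inner <- 10:(length(calls) - 9)
    at <- sample(inner, sample(1:3, 1))
    at <- at[!duplicated(at %/% 3)]
    calls[at] <- vapply(calls[at], function(v) {
      sample(setdiff(c("A", "H", "B"), v), 1)
    }, "")
    ids <- as.character(seq_along(calls))
    fwd <- scan_crossovers(calls, ids, config = cfg)
    bwd <- scan_crossovers(rev(calls), rev(ids), config = cfg)
    expect_equal(nrow(fwd), nrow(bwd))
    expect_equal(sort(fwd$multiplicity), sort(bwd$multiplicity))
  }
})

test_that("family masks come from the F2 genotype or are inferred", {
  mm <- toy_map(4)
  f2 <- dplyr::bind_cols(
    tibble::tibble(family_id = "f1"),
    tibble::as_tibble(matrix(c("A", "H", "H", "B"), nrow = 1,
                             dimnames = list(NULL, mm$marker_id)))
  )
  geno <- toy_genotypes(list(i1 = c("A", "A", "H", "B"),
                             i2 = c("A", "H", "B", "B")), mm)
  mask <- build_family_masks(geno, f2)
  expect_equal(mask$marker_id, c("m2", "m3"))

  # inference: markers constant within the family are excluded
  inferred <- build_family_masks(geno)
  expect_equal(inferred$marker_id, c("m2", "m3"))

  lone <- toy_genotypes(list(i1 = c("A", "A", "H", "B")), mm)
  expect_warning(res <- build_family_masks(lone), "fewer than 2")
  expect_equal(nrow(res), 0)
})

test_that("inferred masks recover the true heterozygous set", {
  sim <- small_sim(seed = 77, n_families = 3, n_f3 = 8, n_markers = 400)
  inferred <- build_family_masks(sim$genotypes)
  truth <- sim$truth$f2_informative
  # with >= 6 clean F3s per family the inferred set equals the truth for
  # nearly every marker (an F2-het marker escapes only if segregation is
  # degenerate in the sample)
  for (f in unique(truth$family_id)) {
    a <- sort(inferred$marker_id[inferred$family_id == f])
    b <- sort(truth$marker_id[truth$family_id == f])
    expect_gt(length(intersect(a, b)) / length(union(a, b)), 0.98)
    expect_true(all(a %in% b))  # inference never invents informativeness
  }
})

test_that("population calling is additive and order-invariant", {
  mm <- toy_map(8)
  calls <- c("A", "A", "A", "A", "H", "H", "H", "H")
  rows <- rep(list(calls), 10)
  names(rows) <- paste0("i", 1:10)
  geno <- toy_genotypes(rows, mm)
  ev <- call_crossovers(geno, mm)
  expect_equal(nrow(ev), 10)

  shuffled <- geno[sample(1:10), ]
  ev2 <- call_crossovers(shuffled, mm)
  expect_equal(dplyr::arrange(ev, individual_id),
               dplyr::arrange(ev2, individual_id))
})

test_that("family masking restricts calling to informative markers", {
  mm <- toy_map(8)
  geno <- toy_genotypes(list(i1 = c("A", "A", "A", "A", "B", "B", "B", "B")),
                        mm)
  masks <- tibble::tibble(family_id = "fam1",
                          marker_id = paste0("m", c(1, 2, 3, 4)))
  # the switch lies outside the informative region: nothing is scored
  expect_equal(nrow(call_crossovers(geno, mm, masks)), 0)
  masks_all <- tibble::tibble(family_id = "fam1", marker_id = mm$marker_id)
  expect_equal(call_crossovers(geno, mm, masks_all)$multiplicity, 2L)
})
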