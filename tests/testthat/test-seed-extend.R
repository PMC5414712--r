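test_that("seed pairs are exactly the disjoint reverse-complement k-mer pairs", {
  p <- search_params(seed_size = 3, min_arm_length = 3)
  pairs <- enumerate_seed_pairs("ACGAAACGT", 1, p)
  expect_equal(pairs$left_start, 1L)   # "ACG" at 1 pairs "CGT" at 7
  expect_equal(pairs$right_start, 7L)  # the (6,7) pair overlaps and is excluded

  expect_equal(nrow(enumerate_seed_pairs(strrep("A", 40), 1, p)), 0)

  # k-mers containing N can never seed; only the N-free flanking pair
  # (ACG at 1, CGT at 6) survives
  npairs <- enumerate_seed_pairs("ACGNNCGT", 1, p)
  expect_equal(npairs$left_start, 1L)
  expect_equal(npairs$right_start, 6L)
  expect_equal(nrow(enumerate_seed_pairs("ANGNNCGN", 1, p)), 0)

  expect_error(enumerate_seed_pairs("ACGT", 99, p), "out of range")
})

test_that("seed pairs agree with a brute-force position-pair enumeration", {
  # independent oracle: check every (a, b) pair directly
  for (s in 1:5) {
    x <- random_dna(60, seed = 400 + s)
    k <- 3L
    expected <- list()
    for (a in 1:(60 - k + 1)) {
      for (b in (a + k):(60 - k + 1)) {
        left <- substr(x, a, a + k - 1)
        right <- substr(x, b, b + k - 1)
        if (!grepl("N", left) && identical(right, reverse_complement(left))) {
          expected[[length(expected) + 1]] <- c(a, b)
        }
      }
    }
    exp_df <- do.call(rbind, expected)
    got <- enumerate_seed_pairs(x, 1, search_params(seed_size = 3,
                                                    min_arm_length = 3))
    expect_equal(nrow(got), NROW(exp_df))
    if (NROW(exp_df)) {
      exp_df <- exp_df[order(exp_df[, 1], exp_df[, 2]), , drop = FALSE]
      expect_equal(got$left_start, as.integer(exp_df[, 1]))
      expect_equal(got$right_start, as.integer(exp_df[, 2]))
    }
  }
})

test_that("a perfect hairpin extends to its maximal stem", {
  lir <- extend_seed(toy_hairpin, 3, 12, 3, toy_params())
  expect_equal(nrow(lir), 1)
  expect_equal(lir$left_start, 1L)
  expect_equal(lir$left_end, 6L)
  expect_equal(lir$right_start, 11L)
  expect_equal(lir$right_end, 16L)
  expect_equal(lir$spacer, 4L)
  expect_equal(lir$n_defects, 0L)
  expect_equal(lir$repeat_length, 6L)
  expect_true(lir$is_perfect)
  expect_equal(lir$alignment, "MMMMMM")

  # same stem fails a 30-bp length threshold
  expect_equal(nrow(extend_seed(toy_hairpin, 3, 12, 3,
                                search_params(seed_size = 3))), 0)

  expect_error(extend_seed(toy_hairpin, 1, 3, 3, toy_params()),
               "reverse complement|range")
})

test_that("an internal substitution is kept as a mismatch column", {
  arm <- random_dna(32, seed = 11)
  right <- reverse_complement(arm)
  # mutate alignment position 16 of the stem: right-copy index 32 - 16 + 1
  idx <- 17L
  old <- substr(right, idx, idx)
  repl <- setdiff(c("A", "C", "G", "T"),
                  c(old, chartr("ACGT", "TGCA", substr(arm, 16, 16))))[1]
  substr(right, idx, idx) <- repl
  genome <- paste0("AA", arm, "AATTAA", right, "AA")
  p <- search_params(min_arm_length = 30)
  hits <- scan_sequence(genome, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$left_start, 3L)
  expect_equal(hits$left_end, 34L)
  expect_equal(hits$n_defects, 1L)
  expect_equal(substr(hits$alignment, 16, 16), "X")
  expect_equal(hits$mismatch_rate, 1 / 32)
  # the brute-force oracle agrees exactly
  expect_identical(as.data.frame(hits[, cmp_cols]),
                   as.data.frame(brute_force_search(genome, p)[, cmp_cols]))
})

test_that("a planted deletion is recovered as a gap column at exact coordinates", {
  sim <- plant_lirs(3000, plant_spec(arm_length = 45, spacer = 30,
                                     n_indels = 1), seed = 77)
  hits <- scan_sequence(sim$sequence, search_params())
  tr <- sim$truth
  m <- dplyr::semi_join(hits, tr, by = coord_cols)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_defects, 1L)
  expect_equal(m$left_length, 45L)
  expect_equal(m$right_length, 44L)
  expect_true(grepl("R", m$alignment, fixed = TRUE))  # right arm lost a base
  expect_equal(m$repeat_length, 44L)  # stem length is the shorter arm
})

test_that("scan recovers planted repeats and rejects low-complexity stems", {
  sim <- plant_lirs(5000, plant_spec(arm_length = 40, spacer = 10), seed = 7)
  hits <- scan_sequence(sim$sequence, search_params())
  m <- dplyr::semi_join(hits, sim$truth, by = coord_cols)
  expect_equal(nrow(m), 1)

  # low-complexity (TA)n stems are removed by the GC filter
  ta <- strrep("TA", 60)
  p <- search_params()
  expect_equal(nrow(scan_sequence(ta, p)), 0)

  # an AT-rich planted stem (GC ~ 0.06) is removed by the default GC
  # threshold but recovered once the threshold is relaxed, showing the GC
  # filter - not the extension - is what rejects it
  at_arm <- paste0(strrep("TA", 8), "GC", strrep("AT", 7))
  at_genome <- paste0("AA", at_arm, "AAAA", reverse_complement(at_arm), "AA")
  expect_equal(nrow(scan_sequence(at_genome, p)), 0)
  relaxed_gc <- scan_sequence(at_genome, search_params(min_gc = 0))
  expect_gt(nrow(relaxed_gc), 0)
  expect_true(any(relaxed_gc$left_start == 3 & relaxed_gc$left_end == 34 &
                    relaxed_gc$right_start == 39 & relaxed_gc$right_end == 70))

  # sequences shorter than two arms cannot hold a repeat
  expect_equal(nrow(scan_sequence(random_dna(50, 1), p)), 0)
})

test_that("emitted repeats satisfy the structural invariants", {
  all_hits <- list()
  for (s in 1:10) {
    x <- random_dna(1500, seed = 500 + s)
    hits <- scan_sequence(x, search_params(min_arm_length = 15))
    if (nrow(hits) == 0) next
    all_hits[[length(all_hits) + 1]] <- hits
    expect_true(all(hits$left_start <= hits$left_end))
    expect_true(all(hits$left_end < hits$right_start))
    expect_true(all(hits$right_start <= hits$right_end))
    expect_true(all(hits$spacer == hits$right_start - hits$left_end - 1))
    expect_true(all(hits$spacer >= 0))
    expect_true(all(hits$repeat_length ==
                      pmin(hits$left_length, hits$right_length)))
    expect_true(all(hits$mismatch_rate ==
                      hits$n_defects / hits$repeat_length))
    # no two consecutive defect columns; terminal columns are matches
    expect_false(any(grepl("[XLR][XLR]", hits$alignment)))
    expect_true(all(startsWith(hits$alignment, "M")))
    expect_true(all(endsWith(hits$alignment, "M")))
    # defect count matches the alignment record
    expect_equal(stringr::str_count(hits$alignment, "[XLR]"), hits$n_defects)
    # gc recomputes from the raw sequence
    arms <- paste0(substring(x, hits$left_start, hits$left_end),
                   substring(x, hits$right_start, hits$right_end))
    expect_equal(hits$gc, gc_fraction(arms))
  }
  expect_gt(length(all_hits), 0)
})

test_that("motif-constrained search keeps repeats with an arm match", {
  arm <- paste0(random_dna(20, seed = 21), "GAATTC", random_dna(18, seed = 22))
  genome <- paste0(random_dna(400, seed = 23), "AA", arm, "AAAATTTTAAAA",
                   reverse_complement(arm), "AA", random_dna(400, seed = 24))
  p <- search_params()
  expect_equal(nrow(motif_search(genome, "GAATTC", p)), 1)
  expect_equal(nrow(motif_search(genome, "CCCCCCCCCC", p)), 0)
  # IUPAC degeneracy: W = A or T, so GAWTC matches GAATC
  arm2 <- paste0(random_dna(20, seed = 31), "GAATC", random_dna(19, seed = 32))
  genome2 <- paste0(random_dna(300, seed = 33), "AA", arm2, "AAAATTTTAAAA",
                    reverse_complement(arm2), "AA", random_dna(300, seed = 34))
  expect_equal(nrow(motif_search(genome2, "GAWTC", p)), 1)
  expect_error(motif_search(genome2, "GAOTC", p), "IUPAC")
})
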