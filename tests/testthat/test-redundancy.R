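test_that("overlap scenarios are classified by their geometry", {
  a <- make_lir(1, 40, 100, 139)
  expect_equal(classify_overlap(a, make_lir(200, 239, 300, 339)), "none")
  # nested entirely inside a's spacer (41..99)
  expect_equal(classify_overlap(a, make_lir(45, 70, 75, 99)), "scenario_D")
  # arm containment
  expect_equal(classify_overlap(make_lir(1, 50, 100, 149),
                                make_lir(10, 40, 110, 140)), "scenario_B")
  # same-side shifted overlap on both sides
  expect_equal(classify_overlap(make_lir(1, 50, 100, 149),
                                make_lir(10, 59, 110, 159)), "scenario_C")
  # single-side overlap only
  expect_equal(classify_overlap(make_lir(1, 40, 100, 139),
                                make_lir(30, 69, 200, 239)), "scenario_A")
  # argument order does not matter
  expect_equal(classify_overlap(make_lir(10, 40, 110, 140),
                                make_lir(1, 50, 100, 149)), "scenario_B")
  expect_error(classify_overlap(a, make_lir(1, 40, 100, 139, seq_id = "t")),
               "different sequences")
})

test_that("redundancy filtering drops the longer-spacer member", {
  # identical repeats collapse to one
  two <- dplyr::bind_rows(make_lir(1, 40, 100, 139), make_lir(1, 40, 100, 139))
  expect_equal(nrow(filter_redundant(two)), 1)

  # scenario C: spacers 100 vs 400, short spacer survives
  c_pair <- dplyr::bind_rows(make_lir(1, 50, 151, 200),     # spacer 100
                             make_lir(11, 60, 461, 510))    # spacer 400
  kept <- filter_redundant(c_pair)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$spacer, 100L)

  # spacer tie: the longer stem survives
  tie <- dplyr::bind_rows(make_lir(1, 30, 131, 160),        # stem 30
                          make_lir(20, 69, 170, 219))       # stem 50, spacer 100
  tie$spacer <- c(100L, 100L)
  kept2 <- filter_redundant(tie)
  expect_equal(kept2$repeat_length, 50L)
})

test_that("nested repeats merge only when same-side arms are within the gap", {
  outer <- make_lir(1, 40, 200, 239)
  inner_close <- make_lir(44, 80, 160, 196)   # gaps 3 and 3 -> merge
  merged <- filter_redundant(dplyr::bind_rows(outer, inner_close))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$left_start, 1L)  # outer stem represents the pair

  inner_far <- make_lir(60, 96, 140, 176)     # gaps 19 and 23 -> keep both
  both <- filter_redundant(dplyr::bind_rows(outer, inner_far))
  expect_equal(nrow(both), 2)

  # one-sided proximity is not enough to merge
  inner_onesided <- make_lir(44, 80, 140, 176)  # left gap 3, right gap 23
  expect_equal(nrow(filter_redundant(dplyr::bind_rows(outer, inner_onesided))),
               2)
})

test_that("filtering is idempotent, order-invariant and scenario-free", {
  set.seed(42)
  rows <- list()
  for (i in 1:12) {
    ls <- sample(1:2000, 1)
    le <- ls + sample(30:60, 1)
    rs <- le + sample(1:400, 1)
    rows[[i]] <- make_lir(ls, le, rs, rs + sample(30:60, 1))
  }
  lirs <- dplyr::bind_rows(rows)
  once <- filter_redundant(lirs)
  expect_lte(nrow(once), nrow(lirs))
  expect_identical(as.data.frame(filter_redundant(once)), as.data.frame(once))
  shuffled <- lirs[sample(nrow(lirs)), ]
  expect_identical(as.data.frame(filter_redundant(shuffled)),
                   as.data.frame(once))
  # every survivor pair is scenario-free (or a legitimately distant nesting)
  if (nrow(once) > 1) {
    for (i in 1:(nrow(once) - 1)) {
      for (j in (i + 1):nrow(once)) {
        sc <- classify_overlap(once[i, ], once[j, ])
        expect_true(sc %in% c("none", "scenario_D"))
        if (sc == "scenario_D") {
          lg <- once$left_start[j] - once$left_end[i] - 1
          rg <- once$right_start[i] - once$right_end[j] - 1
          expect_true(lg > 5 || rg > 5)
        }
      }
    }
  }
  # every survivor was an input
  expect_equal(nrow(dplyr::semi_join(once, lirs, by = coord_cols)),
               nrow(once))
})
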