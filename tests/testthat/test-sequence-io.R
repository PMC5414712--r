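test_that("FASTA records are read in order and normalized to A,C,G,T,N", {
  fa <- write_fasta(list(s = "acgtn", t = "GGGCCC"))
  seqs <- read_dna_fasta(fa)
  expect_equal(seqs$seq_id, c("s", "t"))
  expect_equal(seqs$residues, c("ACGTN", "GGGCCC"))
  expect_equal(seqs$length, c(5L, 6L))

  fa2 <- write_fasta(list(`s desc here` = "ACRYT"))
  expect_warning(seqs2 <- read_dna_fasta(fa2), "ambiguity")
  expect_equal(seqs2$seq_id, "s")  # header truncated at whitespace
  expect_equal(seqs2$residues, "ACNNT")
})

test_that("FASTA reading rejects missing files, empty records and garbage", {
  expect_error(read_dna_fasta(tempfile()), "not found")
  fa <- write_fasta(list(good = "ACGT", empty = ""))
  expect_error(read_dna_fasta(fa), "empty")
  bad <- tempfile()
  writeLines(c("this is", "not fasta"), bad)
  expect_error(read_dna_fasta(bad))
})

test_that("reverse complement handles canonical cases and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "invalid")
  for (s in 1:20) {
    x <- random_dna(sample(1:200, 1), seed = s)
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_identical(gc_fraction(x),
                     gc_fraction(reverse_complement(x)))
  }
})

test_that("GC fraction is (G+C)/(A+C+G+T) with N excluded", {
  expect_equal(gc_fraction(c("ATAT", "GCGC", "GCAT")), c(0, 1, 0.5))
  expect_equal(gc_fraction("GCNN"), 1)
  expect_true(is.na(gc_fraction("NNN")))
  expect_error(gc_fraction(""), "non-empty")
})

test_that("the TSV report round-trips integer fields and flags", {
  lir <- make_lir(3801595, 3801626, 3801662, 3801693)
  out <- tempfile(fileext = ".tsv")
  write_lir_table(lir, out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(back$repeat_length, 32)
  expect_equal(back$spacer, 35)
  expect_equal(back$left_start, 3801595)
  expect_equal(back$right_end, 3801693)
  expect_equal(back$recombinogenic, "no")  # delta 32/35 < 1, perfect stem

  # a recombinogenic palindrome-like repeat gets flag "yes"
  rec <- make_lir(1, 40, 51, 90)
  write_lir_table(rec, out)
  expect_equal(readr::read_tsv(out, show_col_types = FALSE)$recombinogenic,
               "yes")

  write_lir_table(make_lir(1, 40, 51, 90)[0, ], out)
  empty <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("seq_id", "delta", "recombinogenic") %in% names(empty)))
})

test_that("BED output is 0-based half-open, two stranded arms per repeat", {
  lirs <- dplyr::bind_rows(make_lir(1, 6, 11, 16), make_lir(100, 139, 200, 239))
  out <- tempfile(fileext = ".bed")
  write_bed(lirs, out)
  bed <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), 4)
  expect_equal(bed$V2[1], 0)   # 1-based start 1 -> BED start 0
  expect_equal(bed$V3[1], 6)
  expect_setequal(unique(bed$V6), c("+", "-"))
  # arms of one repeat share a name and describe the same intervals as TSV
  expect_equal(sum(bed$V4 == bed$V4[1]), 2)
  left <- bed[bed$V6 == "+", ]
  expect_equal(left$V2 + 1, lirs$left_start)
  expect_equal(left$V3, lirs$left_end)

  write_bed(lirs[0, ], out)
  expect_equal(length(readLines(out)), 0)
})

test_that("search parameter validation enforces the threshold invariants", {
  p <- search_params()
  expect_s3_class(p, "lir_params")
  expect_equal(p$window_size, 2000L)
  expect_equal(p$min_arm_length, 30L)
  expect_equal(p$seed_size, 5L)
  expect_equal(p$max_mismatch_rate, 0.15)
  expect_equal(p$min_gc, 0.20)
  expect_equal(p$merge_gap, 5L)
  expect_error(search_params(seed_size = 0), "seed_size")
  expect_error(search_params(seed_size = 40, min_arm_length = 30), "seed_size")
  expect_error(search_params(min_arm_length = 3000), "window_size")
  expect_error(search_params(max_mismatch_rate = 1.2), "mismatch")
  expect_error(search_params(min_gc = 1), "min_gc")
})
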