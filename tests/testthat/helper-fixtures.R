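# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Map LIR coordinates found on the reverse complement of a length-n
# sequence back to the forward strand (arms swap roles).
map_rc_coords <- function(lirs, n) {
  out <- tibble::tibble(
    left_start = n - lirs$right_end + 1L,
    left_end = n - lirs$right_start + 1L,
    right_start = n - lirs$left_end + 1L,
    right_end = n - lirs$left_start + 1L
  )
  dplyr::arrange(out, left_start, right_start)
}

coord_cols <- c("left_start", "left_end", "right_start", "right_end")
cmp_cols <- c(coord_cols, "n_defects", "alignment")

coords_of <- function(lirs) {
  as.data.frame(dplyr::arrange(lirs[, coord_cols],
                               left_start, right_start))
}

# A small toy stem-loop: 6-bp arms around a 4-bp loop.
toy_hairpin <- paste0("GCCATT", "AAAA", "AATGGC")
toy_params <- function(...) {
  search_params(seed_size = 3, min_arm_length = 6, window_size = 2000, ...)
}

# Minimal LIR row for redundancy tests driven by coordinates alone.
make_lir <- function(ls, le, rs, re, seq_id = "s") {
  ll <- le - ls + 1L
  rl <- re - rs + 1L
  tibble::tibble(
    seq_id = seq_id,
    left_start = as.integer(ls), left_end = as.integer(le),
    right_start = as.integer(rs), right_end = as.integer(re),
    left_length = ll, right_length = rl,
    repeat_length = pmin(ll, rl),
    n_defects = 0L, mismatch_rate = 0,
    spacer = as.integer(rs - le - 1L), gc = 0.5,
    alignment = strrep("M", min(ll, rl)), is_perfect = ll == rl
  )
}

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}
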