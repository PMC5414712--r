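#' Enumerate reverse-complement seed pairs inside one window
#'
#' Finds every ordered pair of disjoint k-mers within the window
#' `[window_start, window_start + window_size - 1]` (clipped to the sequence
#' end) such that the right k-mer is the reverse complement of the left one.
#' k-mers containing `N` are never used: `N` cannot pair.
#'
#' @param seq A DNA string over `A,C,G,T,N`, or a one-row tibble from
#'   [read_dna_fasta()].
#' @param window_start 1-based start of the window.
#' @param params A [search_params()] object; `seed_size` and `window_size`
#'   are used.
#' @return A tibble with columns `left_start`, `right_start`, `k`, ordered
#'   by (`left_start`, `right_start`).
#' @examples
#' enumerate_seed_pairs("ACGAAACGT", 1, search_params(seed_size = 3,
#'   min_arm_length = 3))
#' @export
enumerate_seed_pairs <- function(seq, window_start = 1L, params = search_params()) {
  residues <- resolve_residues(seq)
  params <- check_params(params)
  n <- nchar(residues)
  if (window_start < 1L || window_start > max(n, 1L)) {
    stop("`window_start` out of range", call. = FALSE)
  }
  k <- params$seed_size
  win_end <- min(n, window_start + params$window_size - 1L)
  empty <- tibble::tibble(left_start = integer(), right_start = integer(),
                          k = integer())
  if (win_end - window_start + 1L < 2L * k) {
    return(empty)
  }
  starts <- window_start:(win_end - k + 1L)
  kmers <- substring(residues, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(empty)
  pos <- split(starts[ok], kmers[ok])
  nm <- names(pos)
  partner <- reverse_complement(nm)
  has <- partner %in% nm
  if (!any(has)) return(empty)
  lefts <- pos[nm[has]]
  rights <- pos[partner[has]]
  left_all <- unlist(Map(function(l, r) rep(l, each = length(r)),
                         lefts, rights), use.names = FALSE)
  right_all <- unlist(Map(function(l, r) rep.int(r, length(l)),
                          lefts, rights), use.names = FALSE)
  keep <- right_all > left_all + k - 1L  # seeds disjoint, left precedes right
  out <- tibble::tibble(left_start = as.integer(left_all[keep]),
                        right_start = as.integer(right_all[keep]),
                        k = k)
  dplyr::arrange(out, .data$left_start, .data$right_start)
}

#' Extend one seed pair into a long inverted repeat
#'
#' Grows the seed bidirectionally. Inward extension (toward the spacer)
#' stops when the arms would meet, so the spacer stays non-negative; a
#' spacer of 0 (a true palindrome) is allowed. Outward extension has no
#' length limit. In both directions a single mismatch or one-base indel is
#' tolerated only when the next column pairs again, so two consecutive
#' defects terminate extension and the stem always starts and ends with
#' matched columns.
#'
#' The candidate is kept only if the stem length (the shorter arm) reaches
#' `min_arm_length`, the mismatch rate (defects per stem length) is below
#' `max_mismatch_rate`, and the GC fraction of the two arms exceeds
#' `min_gc`.
#'
#' @inheritParams enumerate_seed_pairs
#' @param left_start,right_start 1-based start positions of the paired
#'   seeds (as returned by [enumerate_seed_pairs()]).
#' @param k Seed length; defaults to `params$seed_size`.
#' @param seq_id Sequence name recorded in the result.
#' @return A one-row LIR tibble, or a zero-row tibble if the extension does
#'   not pass the acceptance filters.
#' @export
extend_seed <- function(seq, left_start, right_start, k = NULL,
                        params = search_params(), seq_id = "seq") {
  residues <- resolve_residues(seq)
  if (!is.null(attr(residues, "seq_id")) && missing(seq_id)) {
    seq_id <- attr(residues, "seq_id")
  }
  params <- check_params(params)
  if (is.null(k)) k <- params$seed_size
  check_seed_pair(residues, left_start, right_start, k)
  ext <- extend_anchors_cpp(residues, as.integer(left_start),
                            as.integer(right_start + k - 1L))
  out <- finalize_lirs(residues, ext, seq_id)
  apply_lir_filters(out, params)
}

#' Scan a sequence for primary long inverted repeats
#'
#' Slides a window of `window_size` bp across the sequence with 50%
#' overlap, enumerates every reverse-complement seed pair in each window,
#' extends each pair with [extend_seed()]'s rules, applies the acceptance
#' filters, and deduplicates candidates that are reachable from more than
#' one seed. The result is the deterministic set of primary (unfiltered for
#' redundancy) LIRs sorted by (`left_start`, `right_start`).
#'
#' @inheritParams enumerate_seed_pairs
#' @param seq_id Sequence name recorded in the result; taken from the input
#'   tibble when available.
#' @return An LIR tibble (see [find_lirs()] for the column set).
#' @export
scan_sequence <- function(seq, params = search_params(), seq_id = NULL) {
  residues <- resolve_residues(seq)
  if (is.null(seq_id)) {
    seq_id <- attr(residues, "seq_id") %||% "seq"
  }
  params <- check_params(params)
  n <- nchar(residues)
  if (n < 2L * params$min_arm_length) {
    return(empty_lir_tbl())
  }
  W <- params$window_size
  stride <- max(1L, W %/% 2L)
  last <- max(1L, n - W + 1L)
  window_starts <- unique(c(seq.int(1L, last, by = stride), last))
  pairs <- dplyr::distinct(dplyr::bind_rows(
    lapply(window_starts, function(w) {
      enumerate_seed_pairs(residues, w, params)
    })
  ))
  if (nrow(pairs) == 0L) {
    return(empty_lir_tbl())
  }
  ext <- extend_anchors_cpp(residues, pairs$left_start,
                            pairs$right_start + pairs$k - 1L)
  out <- finalize_lirs(residues, ext, seq_id)
  out <- apply_lir_filters(out, params)
  dedup_lirs(out)
}

# ---- internal helpers -------------------------------------------------------

# Accepts a plain string or a one-row tibble/list with a `residues` field;
# attaches the seq_id as an attribute when known.
#' @keywords internal
resolve_residues <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) {
    res <- normalize_residues(seq)
    return(res)
  }
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1L || !"residues" %in% names(seq)) {
      stop("expected a single DNA string or a one-row tibble with a ",
           "`residues` column", call. = FALSE)
    }
    res <- normalize_residues(seq$residues[[1]])
    if ("seq_id" %in% names(seq)) attr(res, "seq_id") <- seq$seq_id[[1]]
    return(res)
  }
  stop("expected a single DNA string or a one-row tibble with a ",
       "`residues` column", call. = FALSE)
}

#' @keywords internal
check_seed_pair <- function(residues, left_start, right_start, k) {
  n <- nchar(residues)
  if (left_start < 1L || right_start + k - 1L > n ||
      left_start + k - 1L >= right_start) {
    stop("seed pair out of range or overlapping", call. = FALSE)
  }
  left <- substring(residues, left_start, left_start + k - 1L)
  right <- substring(residues, right_start, right_start + k - 1L)
  if (!identical(right, reverse_complement(left))) {
    stop("right seed is not the reverse complement of the left seed",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Turn raw extension records into the full LIR statistics table.
# Stem length (`repeat_length`) is the shorter arm; the mismatch rate is
# defects per stem length; GC is computed over both arms together.
#' @keywords internal
finalize_lirs <- function(residues, ext, seq_id) {
  ext <- tibble::as_tibble(ext)
  if (nrow(ext) == 0L) return(empty_lir_tbl())
  left_length <- ext$left_end - ext$left_start + 1L
  right_length <- ext$right_end - ext$right_start + 1L
  repeat_length <- pmin(left_length, right_length)
  arms <- paste0(
    substring(residues, ext$left_start, ext$left_end),
    substring(residues, ext$right_start, ext$right_end)
  )
  tibble::tibble(
    seq_id = seq_id,
    left_start = ext$left_start, left_end = ext$left_end,
    right_start = ext$right_start, right_end = ext$right_end,
    left_length = left_length, right_length = right_length,
    repeat_length = repeat_length,
    n_defects = ext$n_defects,
    mismatch_rate = ext$n_defects / repeat_length,
    spacer = ext$right_start - ext$left_end - 1L,
    gc = gc_fraction(arms),
    alignment = as.character(ext$alignment),
    is_perfect = ext$n_defects == 0L & left_length == right_length
  )
}

#' @keywords internal
apply_lir_filters <- function(lirs, params) {
  dplyr::filter(
    lirs,
    .data$repeat_length >= params$min_arm_length,
    .data$mismatch_rate < params$max_mismatch_rate,
    !is.na(.data$gc) & .data$gc > params$min_gc
  )
}

# Deduplicate on coordinates, deterministically keeping the variant with the
# fewest defects (then the lexicographically first alignment).
#' @keywords internal
dedup_lirs <- function(lirs) {
  lirs |>
    dplyr::arrange(.data$seq_id, .data$left_start, .data$right_start,
                   .data$left_end, .data$right_end, .data$n_defects,
                   .data$alignment) |>
    dplyr::distinct(.data$seq_id, .data$left_start, .data$left_end,
                    .data$right_start, .data$right_end, .keep_all = TRUE) |>
    dplyr::arrange(.data$seq_id, .data$left_start, .data$right_start)
}

#' @keywords internal
empty_lir_tbl <- function() {
  tibble::tibble(
    seq_id = character(), left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(),
    left_length = integer(), right_length = integer(),
    repeat_length = integer(), n_defects = integer(),
    mismatch_rate = double(), spacer = integer(), gc = double(),
    alignment = character(), is_perfect = logical()
  )
}
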