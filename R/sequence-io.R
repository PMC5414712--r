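#' Read DNA sequences from a FASTA file
#'
#' Reads one or more records and normalises them to the internal alphabet:
#' lowercase letters are uppercased and IUPAC ambiguity codes other than `N`
#' (R, Y, S, W, K, M, B, D, H, V) are mapped to `N` with a warning. `N` can
#' never pair with anything, so ambiguous positions are simply opaque to the
#' repeat search. Record ids are taken from the header up to the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `seq_id`, `residues`
#'   (a string over `A,C,G,T,N`) and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "acgtn"), fa)
#' read_dna_fasta(fa)
#' @export
read_dna_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse ", path, " as FASTA: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  res <- as.character(set)
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[widths == 0L], collapse = ", "), call. = FALSE)
  }
  residues <- vapply(res, normalize_residues, character(1), USE.NAMES = FALSE)
  tibble::tibble(seq_id = ids, residues = residues, length = nchar(residues))
}

#' @keywords internal
normalize_residues <- function(x) {
  up <- toupper(x)
  bad <- gsub("[ACGTN]", "", up)
  if (nzchar(bad)) {
    ambig <- gsub("[RYSWKMBDHV]", "", bad)
    if (nzchar(ambig)) {
      stop("invalid DNA characters: ",
           paste(unique(strsplit(ambig, "")[[1]]), collapse = ", "),
           call. = FALSE)
    }
    warning("IUPAC ambiguity codes mapped to N (",
            sum(nchar(bad)), " position(s))", call. = FALSE)
    up <- gsub("[RYSWKMBDHV]", "N", up)
  }
  up
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its argument. `N` complements to `N`; any other character
#' is an error. The empty string maps to itself.
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid DNA characters in input; expected A,C,G,T,N", call. = FALSE)
  }
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' GC fraction of DNA strings
#'
#' `(G + C) / (A + C + G + T)`, vectorised. `N` positions are excluded from
#' the denominator; a string with no unambiguous base yields `NA`.
#'
#' @param x Character vector of non-empty DNA strings over `A,C,G,T,N`.
#' @return Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @examples
#' gc_fraction(c("ATAT", "GCGC", "GCAT"))
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x))
  if (any(!nzchar(x) | is.na(x))) {
    stop("gc_fraction() requires non-empty sequences", call. = FALSE)
  }
  gc <- stringr::str_count(x, "[GC]")
  acgt <- stringr::str_count(x, "[ACGT]")
  ifelse(acgt > 0L, gc / acgt, NA_real_)
}

#' Write an LIR report as tab-separated text
#'
#' One row per repeat with the 1-based inclusive arm coordinates, the stem
#' statistics, and the recombinogenicity call. `mismatch_rate` and `gc` are
#' printed truncated to three decimals (matching the convention of published
#' repeat tables); `delta` is printed as `Inf` for spacer-free palindromes;
#' the `recombinogenic` flag is written as `yes`/`no`. If the input has not
#' been classified yet, `delta` and `recombinogenic` are computed on the fly.
#'
#' @param lirs A tibble of LIRs (as returned by [scan_sequence()],
#'   [filter_redundant()] or [find_lirs()]), sorted by
#'   (`seq_id`, `left_start`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lir_table <- function(lirs, path) {
  lirs <- as_lir_tbl(lirs)
  if (!"delta" %in% names(lirs)) {
    lirs <- classify_recombinogenic(lirs)
  }
  out <- tibble::tibble(
    seq_id = lirs$seq_id,
    left_start = lirs$left_start,
    left_end = lirs$left_end,
    right_start = lirs$right_start,
    right_end = lirs$right_end,
    repeat_length = lirs$repeat_length,
    n_defects = lirs$n_defects,
    mismatch_rate = sprintf("%.3f", trunc(lirs$mismatch_rate * 1000) / 1000),
    spacer = lirs$spacer,
    gc = sprintf("%.3f", trunc(lirs$gc * 1000) / 1000),
    delta = ifelse(is.infinite(lirs$delta), "Inf",
                   sprintf("%.3f", lirs$delta)),
    recombinogenic = ifelse(lirs$recombinogenic, "yes", "no")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write LIR arms as a BED6 file
#'
#' Emits two intervals per repeat (one per arm) in 0-based half-open BED
#' coordinates. Both arms of a repeat share a `name`; the left arm is
#' reported on strand `+` and the right arm on strand `-`, reflecting the
#' antiparallel pairing of the stem.
#'
#' @inheritParams write_lir_table
#' @return `path`, invisibly.
#' @export
write_bed <- function(lirs, path) {
  lirs <- as_lir_tbl(lirs)
  if (nrow(lirs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- sprintf("LIR_%s_%d", lirs$seq_id, seq_len(nrow(lirs)))
  bed <- rbind(
    data.frame(chrom = lirs$seq_id, start = lirs$left_start - 1L,
               end = lirs$left_end, name = name, score = 0L, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(chrom = lirs$seq_id, start = lirs$right_start - 1L,
               end = lirs$right_end, name = name, score = 0L, strand = "-",
               stringsAsFactors = FALSE)
  )
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Coerce and sanity-check a data frame of LIRs.
#' @keywords internal
as_lir_tbl <- function(lirs) {
  lirs <- tibble::as_tibble(lirs)
  needed <- c("seq_id", "left_start", "left_end", "right_start", "right_end")
  missing <- setdiff(needed, names(lirs))
  if (length(missing)) {
    stop("LIR table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lirs
}
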