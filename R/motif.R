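#' Convert an IUPAC nucleotide motif to a regular expression
#'
#' Each IUPAC code expands to its base class (`W` to `[AT]`, `N` to
#' `[ACGT]`, ...). Ambiguous sequence positions (`N` in the scanned DNA)
#' never satisfy a motif.
#'
#' @param motif IUPAC motif string.
#' @return A regular expression string.
#' @keywords internal
iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) {
    stop("invalid IUPAC characters in motif: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste(map[chars], collapse = "")
}

#' Find long inverted repeats with a motif in one arm
#'
#' Runs the full search ([scan_sequence()] followed by
#' [filter_redundant()]) and keeps only the repeats in which at least one
#' arm contains a substring matching `motif` under IUPAC semantics. Useful
#' when one repeat copy is expected to carry a known site (e.g. a
#' restriction site or a primer).
#'
#' @inheritParams scan_sequence
#' @param motif IUPAC motif string; its length must not exceed the window
#'   size.
#' @return A filtered LIR tibble.
#' @export
motif_search <- function(seq, motif, params = search_params(), seq_id = NULL) {
  params <- check_params(params)
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("`motif` must be a non-empty IUPAC string", call. = FALSE)
  }
  if (nchar(motif) > params$window_size) {
    stop("motif longer than the search window", call. = FALSE)
  }
  rx <- iupac_to_regex(motif)
  residues <- resolve_residues(seq)
  lirs <- scan_sequence(residues, params,
                        seq_id = seq_id %||% attr(residues, "seq_id") %||% "seq")
  lirs <- filter_redundant(lirs, params)
  if (nrow(lirs) == 0L) return(lirs)
  left_arm <- substring(residues, lirs$left_start, lirs$left_end)
  right_arm <- substring(residues, lirs$right_start, lirs$right_end)
  keep <- stringr::str_detect(left_arm, rx) |
    stringr::str_detect(right_arm, rx)
  lirs[keep, , drop = FALSE]
}
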