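#' Find long inverted repeats in a set of DNA sequences
#'
#' The full analysis pipeline: per record, scan for primary LIRs
#' ([scan_sequence()]), remove redundant overlapping repeats
#' ([filter_redundant()]), and call recombinogenicity
#' ([classify_recombinogenic()]). Records are processed independently with
#' per-record coordinates.
#'
#' @param seqs A tibble of sequences as returned by [read_dna_fasta()] (or
#'   a path to a FASTA file).
#' @param params A [search_params()] object.
#' @param motif Optional IUPAC motif; when given, only repeats with a
#'   motif match in at least one arm are kept (see [motif_search()]).
#' @return An `lir_result` tibble with one row per reported repeat and
#'   columns `seq_id`, `left_start`, `left_end`, `right_start`,
#'   `right_end`, `left_length`, `right_length`, `repeat_length`
#'   (stem length, the shorter arm), `n_defects`, `mismatch_rate`,
#'   `spacer`, `gc`, `alignment`, `is_perfect`, `delta`, `recombinogenic`.
#'   Per-record scan summaries (primary, perfect/imperfect, filtered and
#'   recombinogenic counts) are attached as the `"scan_summary"` attribute
#'   and available via [glance()].
#' @examples
#' sim <- plant_lirs(4000, plant_spec(arm_length = 40, spacer = 12), seed = 1)
#' find_lirs(sim$sequence)
#' @export
find_lirs <- function(seqs, params = search_params(), motif = NULL) {
  params <- check_params(params)
  if (is.character(seqs) && length(seqs) == 1L) {
    seqs <- read_dna_fasta(seqs)
  }
  if (!is.data.frame(seqs) || !all(c("seq_id", "residues") %in% names(seqs))) {
    stop("`seqs` must be a FASTA path or a tibble with `seq_id` and ",
         "`residues` columns", call. = FALSE)
  }
  if (anyDuplicated(seqs$seq_id)) {
    stop("duplicate sequence ids in input", call. = FALSE)
  }

  per_record <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$seq_id[[i]]
    residues <- seqs$residues[[i]]
    primary <- scan_sequence(residues, params, seq_id = id)
    filtered <- filter_redundant(primary, params)
    classified <- classify_recombinogenic(filtered)
    if (!is.null(motif)) {
      rx <- iupac_to_regex(motif)
      la <- substring(residues, classified$left_start, classified$left_end)
      ra <- substring(residues, classified$right_start, classified$right_end)
      classified <- classified[stringr::str_detect(la, rx) |
                                 stringr::str_detect(ra, rx), , drop = FALSE]
    }
    summary <- tibble::tibble(
      seq_id = id,
      n_primary = nrow(primary),
      n_perfect = sum(primary$is_perfect),
      n_imperfect = sum(!primary$is_perfect),
      n_filtered = nrow(filtered),
      n_reported = nrow(classified),
      n_recombinogenic = sum(classified$recombinogenic)
    )
    list(lirs = classified, summary = summary)
  })

  out <- dplyr::bind_rows(lapply(per_record, `[[`, "lirs"))
  if (nrow(out) == 0L) {
    out <- classify_recombinogenic(empty_lir_tbl())
  }
  attr(out, "scan_summary") <- dplyr::bind_rows(lapply(per_record, `[[`,
                                                       "summary"))
  attr(out, "params") <- params
  class(out) <- c("lir_result", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a repeat search
#'
#' Totals across all scanned records: primary repeat count with its
#' perfect/imperfect split, the count surviving redundancy filtering, and
#' the number called recombinogenic. `n_perfect + n_imperfect` always
#' equals `n_primary`, and `n_filtered <= n_primary`.
#'
#' @param x An `lir_result` from [find_lirs()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lir_result <- function(x, ...) {
  s <- attr(x, "scan_summary")
  tibble::tibble(
    n_sequences = nrow(s),
    n_primary = sum(s$n_primary),
    n_perfect = sum(s$n_perfect),
    n_imperfect = sum(s$n_imperfect),
    n_filtered = sum(s$n_filtered),
    n_reported = sum(s$n_reported),
    n_recombinogenic = sum(s$n_recombinogenic)
  )
}

#' Tidy a repeat search result
#'
#' Returns the result as a plain tibble (one row per repeat), dropping the
#' result class and attached attributes.
#'
#' @param x An `lir_result` from [find_lirs()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lir_result <- function(x, ...) {
  out <- x
  attr(out, "scan_summary") <- NULL
  attr(out, "params") <- NULL
  class(out) <- setdiff(class(out), "lir_result")
  tibble::as_tibble(out)
}

#' @export
print.lir_result <- function(x, ...) {
  s <- attr(x, "scan_summary")
  if (!is.null(s)) {
    cat(sprintf(
      "# Long inverted repeats: %d reported (%d primary, %d after redundancy removal, %d recombinogenic)\n",
      sum(s$n_reported), sum(s$n_primary), sum(s$n_filtered),
      sum(s$n_recombinogenic)))
  }
  NextMethod()
}

#' Run the repeat search end to end and write report files
#'
#' Reads a FASTA file, runs [find_lirs()], and writes the TSV report (and
#' optionally a BED6 file of arm intervals). A per-record summary is
#' printed unless `quiet = TRUE`. This is the function behind the
#' command-line interface (`inst/cli/lirscan.R`).
#'
#' @param input Path to a FASTA file.
#' @param output_prefix Path prefix for the report files
#'   (`<prefix>.tsv`, `<prefix>.bed`).
#' @param params A [search_params()] object.
#' @param motif Optional IUPAC motif constraint (see [find_lirs()]).
#' @param recombinogenic_only Keep only repeats called recombinogenic.
#' @param emit_bed Also write the BED6 arm intervals.
#' @param quiet Suppress the run summary messages.
#' @return The `lir_result` tibble, invisibly.
#' @export
run_lir_scan <- function(input, output_prefix,
                         params = search_params(), motif = NULL,
                         recombinogenic_only = FALSE, emit_bed = FALSE,
                         quiet = FALSE) {
  if (!nzchar(input) || !nzchar(output_prefix)) {
    stop("`input` and `output_prefix` must be non-empty paths", call. = FALSE)
  }
  params <- check_params(params)
  result <- find_lirs(input, params, motif = motif)
  reported <- if (recombinogenic_only) {
    dplyr::filter(tidy(result), .data$recombinogenic)
  } else {
    tidy(result)
  }
  write_lir_table(reported, paste0(output_prefix, ".tsv"))
  if (emit_bed) {
    write_bed(reported, paste0(output_prefix, ".bed"))
  }
  if (!quiet) {
    s <- attr(result, "scan_summary")
    for (i in seq_len(nrow(s))) {
      message(sprintf(
        "%s: %d primary LIRs (%d perfect, %d imperfect); %d after redundancy removal; %d recombinogenic",
        s$seq_id[i], s$n_primary[i], s$n_perfect[i], s$n_imperfect[i],
        s$n_filtered[i], s$n_recombinogenic[i]))
    }
    message("report written to ", output_prefix, ".tsv")
  }
  invisible(result)
}
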