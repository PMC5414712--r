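#' Stem-to-spacer ratio of an inverted repeat
#'
#' The ratio of repeat (stem) length to internal spacer length, the key
#' geometric predictor of recombinogenic capacity: a long stem closing over
#' a short loop. A spacer of zero (a perfect palindrome) yields `Inf`.
#'
#' @param arm_length Stem length in bp (positive).
#' @param spacer Internal spacer length in bp (non-negative).
#' @return Numeric vector of ratios (dimensionless), `Inf` where
#'   `spacer == 0`.
#' @examples
#' delta_ratio(35, 20)
#' delta_ratio(30, 0)
#' @export
delta_ratio <- function(arm_length, spacer) {
  if (any(arm_length <= 0, na.rm = TRUE)) {
    stop("`arm_length` must be positive", call. = FALSE)
  }
  if (any(spacer < 0, na.rm = TRUE)) {
    stop("`spacer` must be non-negative", call. = FALSE)
  }
  ifelse(spacer == 0, Inf, arm_length / spacer)
}

#' Predict whether inverted repeats are recombinogenic
#'
#' A repeat is called recombinogenic from three characteristics: spacer
#' size, arm identity, and the stem-to-spacer ratio delta. For a perfectly
#' matched repeat the call is `delta > 1` (spacer shorter than the stem).
#' For an imperfect repeat the call is `delta >= 100 * mismatch_rate`,
#' i.e. delta is compared against the mismatch rate expressed in percent.
#' This percent-scale comparison is the calibration that reproduces the
#' published recombinogenic/non-recombinogenic split of the bundled
#' reference coordinate set (see [lir_reference_coords()]) and is consistent
#' with the experimental observation that closely spaced (<20 bp) inverted
#' repeats with >85% identity are recombination-prone while delta values
#' above ~16 mark strong recombinogenic ability. A plain same-scale reading
#' of the rule would call nearly every repeat with a nonzero mismatch rate
#' recombinogenic and does not reproduce the reference calls; the methods
#' vignette discusses this choice.
#'
#' @param repeat_length Stem length(s) in bp.
#' @param mismatch_rate Defects per stem length, as a fraction.
#' @param spacer Internal spacer length(s) in bp.
#' @return Logical vector of recombinogenicity calls.
#' @examples
#' is_recombinogenic(35, 0, 20)       # short loop, perfect stem: TRUE
#' is_recombinogenic(32, 0.031, 35)   # delta 0.91 < 3.1: FALSE
#' @export
is_recombinogenic <- function(repeat_length, mismatch_rate, spacer) {
  if (any(mismatch_rate < 0, na.rm = TRUE)) {
    stop("`mismatch_rate` must be non-negative", call. = FALSE)
  }
  d <- delta_ratio(repeat_length, spacer)
  ifelse(mismatch_rate == 0, d > 1, d >= 100 * mismatch_rate)
}

#' Add recombinogenicity calls to an LIR table
#'
#' Appends `delta` and `recombinogenic` columns (see [delta_ratio()] and
#' [is_recombinogenic()]).
#'
#' @param lirs An LIR tibble with `repeat_length`, `mismatch_rate` and
#'   `spacer` columns.
#' @return The input tibble with `delta` and `recombinogenic` appended.
#' @export
classify_recombinogenic <- function(lirs) {
  lirs <- tibble::as_tibble(lirs)
  needed <- c("repeat_length", "mismatch_rate", "spacer")
  missing <- setdiff(needed, names(lirs))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    lirs,
    delta = delta_ratio(.data$repeat_length, .data$spacer),
    recombinogenic = is_recombinogenic(.data$repeat_length,
                                       .data$mismatch_rate, .data$spacer)
  )
}

#' Reference long inverted repeat coordinates
#'
#' A curated reference set of 17 LIRs reported for the 3.8-4.0 Mb region of
#' human chromosome 4 contig NT_022853.16, with the published 1-based arm
#' coordinates, stem length, mismatch rate, spacer size and
#' recombinogenicity call. Used to validate the package's coordinate
#' arithmetic (stem length is the shorter arm; spacer is
#' `right_start - left_end - 1`) and to calibrate the recombinogenicity
#' classifier. Note: the last row's printed spacer (811) is one larger than
#' its own coordinates imply (810); the set is shipped exactly as printed.
#'
#' @return A tibble with columns `left_start`, `left_end`, `right_start`,
#'   `right_end`, `repeat_length`, `mismatch_rate`, `spacer`,
#'   `recombinogenic`.
#' @export
lir_reference_coords <- function() {
  path <- system.file("extdata", "nt022853_reference_lirs.tsv",
                      package = "lirscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
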