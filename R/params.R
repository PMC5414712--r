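#' Search parameters for long inverted repeat detection
#'
#' Bundles every tunable threshold of the search in one validated object.
#' The defaults are the tool's standard operating point: seeds of 5 bp are
#' paired inside a 2000-bp sliding window, extended stems must reach 30 bp,
#' keep their mismatch rate (defects per stem length) below 15% and their
#' arm GC content above 20% (which discards low-complexity stems such as
#' (TA)n runs).
#'
#' @param window_size Sliding window size in bp in which a seed and its
#'   reverse-complement partner must co-occur. Default 2000.
#' @param min_arm_length Minimum stem (arm) length in bp for a primary LIR.
#'   Default 30, applied inclusively.
#' @param seed_size Exact-match seed length in bp. Default 5.
#' @param max_mismatch_rate Strict upper bound on defects per stem length.
#'   Default 0.15.
#' @param min_gc Strict lower bound on the GC fraction of the two arms.
#'   Default 0.20.
#' @param merge_gap Maximum same-side arm separation (bp) at which two
#'   nested repeats are merged into one during redundancy removal. Fixed
#'   default 5.
#' @param restart_spacer_threshold Spacer size (bp) below which the original
#'   search walk moves the window past a found repeat rather than re-seeding
#'   inside its spacer. Retained for interface completeness; the scanner
#'   enumerates all seed pairs per window, which subsumes the restart walk.
#'   Default 5.
#' @return An object of class `lir_params` (a named list).
#' @examples
#' search_params()
#' search_params(min_arm_length = 15)
#' @export
search_params <- function(window_size = 2000L,
                          min_arm_length = 30L,
                          seed_size = 5L,
                          max_mismatch_rate = 0.15,
                          min_gc = 0.20,
                          merge_gap = 5L,
                          restart_spacer_threshold = 5L) {
  p <- list(
    window_size = as.integer(window_size),
    min_arm_length = as.integer(min_arm_length),
    seed_size = as.integer(seed_size),
    max_mismatch_rate = as.numeric(max_mismatch_rate),
    min_gc = as.numeric(min_gc),
    max_consecutive_defects = 2L,  # structural constant of the defect rule
    merge_gap = as.integer(merge_gap),
    restart_spacer_threshold = as.integer(restart_spacer_threshold)
  )
  if (anyNA(p[c("window_size", "min_arm_length", "seed_size",
                "max_mismatch_rate", "min_gc", "merge_gap")], recursive = TRUE)) {
    stop("search parameters must not be NA", call. = FALSE)
  }
  if (!(p$seed_size > 0L && p$seed_size <= p$min_arm_length &&
        p$min_arm_length <= p$window_size)) {
    stop("need 0 < seed_size <= min_arm_length <= window_size", call. = FALSE)
  }
  if (!(p$max_mismatch_rate > 0 && p$max_mismatch_rate < 1)) {
    stop("max_mismatch_rate must be in (0, 1)", call. = FALSE)
  }
  if (!(p$min_gc >= 0 && p$min_gc < 1)) {
    stop("min_gc must be in [0, 1)", call. = FALSE)
  }
  if (p$merge_gap < 0L || p$restart_spacer_threshold < 0L) {
    stop("merge_gap and restart_spacer_threshold must be non-negative",
         call. = FALSE)
  }
  structure(p, class = "lir_params")
}

#' @export
print.lir_params <- function(x, ...) {
  cat("Long inverted repeat search parameters\n")
  cat(sprintf("  window size:        %d bp\n", x$window_size))
  cat(sprintf("  minimum arm length: %d bp\n", x$min_arm_length))
  cat(sprintf("  seed size:          %d bp\n", x$seed_size))
  cat(sprintf("  max mismatch rate:  < %.3f\n", x$max_mismatch_rate))
  cat(sprintf("  min GC fraction:    > %.3f\n", x$min_gc))
  cat(sprintf("  merge gap:          %d bp\n", x$merge_gap))
  invisible(x)
}

#' @keywords internal
check_params <- function(params) {
  if (!inherits(params, "lir_params")) {
    if (is.list(params)) {
      return(do.call(search_params, params[intersect(names(params),
        names(formals(search_params)))]))
    }
    stop("`params` must be created with search_params()", call. = FALSE)
  }
  params
}
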