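#' Classify how two long inverted repeats overlap
#'
#' Redundant primary LIRs arise in repeat-rich genomes in four recurring
#' geometries, distinguished here for the filtering rule:
#'
#' * `scenario_A` - arms of the two repeats overlap on one side only
#'   (start- or end-side overlap of repeat copies).
#' * `scenario_B` - an arm of one repeat is contained within an arm of the
#'   other (a small copy participating in a bigger copy).
#' * `scenario_C` - the same-side arms of the two repeats overlap with a
#'   shift, on both sides.
#' * `scenario_D` - one repeat lies entirely within the internal spacer of
#'   the other (a nested stem-loop).
#' * `none` - no arm overlap and no nesting.
#'
#' Containment (`scenario_B`) takes precedence over shifted overlap
#' (`scenario_C`), which takes precedence over single-side overlap
#' (`scenario_A`); nesting (`scenario_D`) only applies when no arms overlap.
#'
#' @param a,b One-row data frames (or named lists) with fields `seq_id`,
#'   `left_start`, `left_end`, `right_start`, `right_end`. The pair is
#'   oriented internally so the repeat with the smaller `left_start` plays
#'   the role of `a`.
#' @return A string: `"none"`, `"scenario_A"`, `"scenario_B"`,
#'   `"scenario_C"` or `"scenario_D"`.
#' @export
classify_overlap <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(a$seq_id, b$seq_id)) {
    stop("cannot compare LIRs on different sequences", call. = FALSE)
  }
  if (b$left_start < a$left_start ||
      (b$left_start == a$left_start && b$right_start < a$right_start)) {
    tmp <- a; a <- b; b <- tmp
  }
  iv_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  iv_within <- function(s1, e1, s2, e2) s1 >= s2 && e1 <= e2

  arms_a <- list(c(a$left_start, a$left_end), c(a$right_start, a$right_end))
  arms_b <- list(c(b$left_start, b$left_end), c(b$right_start, b$right_end))
  any_overlap <- FALSE
  any_contain <- FALSE
  for (x in arms_a) {
    for (y in arms_b) {
      if (iv_overlap(x[1], x[2], y[1], y[2])) any_overlap <- TRUE
      if (iv_within(x[1], x[2], y[1], y[2]) ||
          iv_within(y[1], y[2], x[1], x[2])) any_contain <- TRUE
    }
  }
  if (!any_overlap) {
    nested <- b$left_start > a$left_end && b$right_end < a$right_start
    return(if (nested) "scenario_D" else "none")
  }
  if (any_contain) return("scenario_B")
  same_left <- iv_overlap(a$left_start, a$left_end, b$left_start, b$left_end)
  same_right <- iv_overlap(a$right_start, a$right_end,
                           b$right_start, b$right_end)
  if (same_left && same_right) return("scenario_C")
  "scenario_A"
}

#' Remove redundant long inverted repeats
#'
#' Applies the pairwise redundancy rules until a fixpoint is reached. For
#' overlapping pairs (scenarios A-C) the member with the longer internal
#' spacer is dropped; spacer ties drop the shorter stem, and remaining ties
#' drop the repeat starting later. For a repeat nested inside another's
#' spacer (scenario D), the two are combined into one reported repeat -
#' represented by the outer stem - when their same-side arms are separated
#' by at most `merge_gap` bp on both sides; nested stems further apart are
#' genuine distinct structures and both are kept.
#'
#' The result is independent of the input order and idempotent.
#'
#' @param lirs An LIR tibble (possibly spanning several sequences; rules are
#'   applied per sequence).
#' @param params A [search_params()] object; `merge_gap` is used.
#' @return The filtered LIR tibble, sorted by
#'   (`seq_id`, `left_start`, `right_start`).
#' @export
filter_redundant <- function(lirs, params = search_params()) {
  params <- check_params(params)
  lirs <- as_lir_tbl(lirs)
  if (nrow(lirs) <= 1L) return(lirs)
  lirs |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::group_modify(~ filter_redundant_one(.x, .y$seq_id, params)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$seq_id, .data$left_start, .data$right_start)
}

#' @keywords internal
filter_redundant_one <- function(d, seq_id, params) {
  d <- dplyr::arrange(d, .data$left_start, .data$right_start)
  d <- dplyr::distinct(d, .data$left_start, .data$left_end,
                       .data$right_start, .data$right_end, .keep_all = TRUE)
  repeat {
    n <- nrow(d)
    if (n <= 1L) break
    drop <- rep(FALSE, n)
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      if (drop[i]) next
      for (j in (i + 1L):n) {
        if (drop[i]) break
        if (drop[j]) next
        sc <- classify_overlap(cbind(seq_id = seq_id, d[i, ]),
                               cbind(seq_id = seq_id, d[j, ]))
        if (sc %in% c("scenario_A", "scenario_B", "scenario_C")) {
          loser <- pick_loser(d, i, j)
          drop[loser] <- TRUE
          changed <- TRUE
        } else if (sc == "scenario_D") {
          left_gap <- d$left_start[j] - d$left_end[i] - 1L
          right_gap <- d$right_start[i] - d$right_end[j] - 1L
          if (left_gap <= params$merge_gap && right_gap <= params$merge_gap) {
            drop[j] <- TRUE  # combined: the outer stem represents the pair
            changed <- TRUE
          }
        }
      }
    }
    d <- d[!drop, , drop = FALSE]
    if (!changed) break
  }
  d
}

# Longer spacer loses; ties lose on shorter stem, then on later start.
#' @keywords internal
pick_loser <- function(d, i, j) {
  if (d$spacer[i] != d$spacer[j]) {
    return(if (d$spacer[i] > d$spacer[j]) i else j)
  }
  if (d$repeat_length[i] != d$repeat_length[j]) {
    return(if (d$repeat_length[i] < d$repeat_length[j]) i else j)
  }
  j
}
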