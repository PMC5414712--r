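#' Specify one planted inverted repeat
#'
#' Describes a repeat to be written into a synthetic genome by
#' [plant_lirs()]: a left arm, a spacer, and a right arm that is the
#' reverse complement of the left arm carrying a chosen number of
#' substitutions and deletions. Defects are placed in the arm interior, at
#' least `seed_size + 1` positions apart, so the plant always retains a
#' clean seed and no two defects are adjacent - otherwise the plant would
#' be undiscoverable by construction of the defect rules.
#'
#' @param arm_length Left arm length in bp.
#' @param spacer Spacer length in bp (>= 0).
#' @param n_substitutions,n_indels Number of substitutions / single-base
#'   deletions applied to the right copy.
#' @param arm_gc GC fraction used when drawing the arm sequence.
#' @param insert_position 1-based genome position of the left arm start, or
#'   `"random"`.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(arm_length, spacer, n_substitutions = 0L,
                       n_indels = 0L, arm_gc = 0.5,
                       insert_position = "random") {
  stopifnot(arm_length >= 1, spacer >= 0,
            n_substitutions >= 0, n_indels >= 0,
            arm_gc >= 0, arm_gc <= 1)
  structure(list(arm_length = as.integer(arm_length),
                 spacer = as.integer(spacer),
                 n_substitutions = as.integer(n_substitutions),
                 n_indels = as.integer(n_indels),
                 arm_gc = as.numeric(arm_gc),
                 insert_position = insert_position),
            class = "plant_spec")
}

#' Generate a synthetic genome with planted inverted repeats
#'
#' Draws an i.i.d. uniform A/C/G/T background and writes each requested
#' repeat into it. A plant consists of a random arm (at the requested GC),
#' a random spacer, and the mutated reverse complement of the arm. Two
#' guard bases flanking each plant, and the outermost spacer bases, are set
#' to `A` so that neither inward nor outward extension can creep past the
#' planted boundaries by chance pairing - planted coordinates are therefore
#' exact ground truth. Around each planted deletion the arm is locally
#' recoded so that the three bases spanning the deletion site are pairwise
#' distinct, which makes the gap column's position in the alignment
#' unambiguous. The generator is deterministic given `seed`.
#'
#' @param genome_length Total genome length in bp.
#' @param specs A list of [plant_spec()] objects (a single spec is
#'   accepted).
#' @param seed Integer seed for all randomness in the generator.
#' @param seq_id Name of the generated sequence.
#' @return A list with `sequence` (a one-row tibble as from
#'   [read_dna_fasta()]) and `truth` (a tibble of planted arm coordinates:
#'   `left_start`, `left_end`, `right_start`, `right_end`, plus the [plant_spec()]
#'   fields).
#' @export
plant_lirs <- function(genome_length, specs, seed, seq_id = "synthetic") {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "plant_spec")))
  genome_length <- as.integer(genome_length)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  bases <- c("A", "C", "G", "T")
  g <- sample(bases, genome_length, replace = TRUE)

  # plant extents include 2 guard bases on each side
  extents <- vapply(specs, function(s) {
    s$arm_length + s$spacer + (s$arm_length - s$n_indels) + 4L
  }, integer(1))
  if (any(extents > genome_length)) {
    stop("plants do not fit in the genome", call. = FALSE)
  }

  # resolve start positions (of the left arm) without overlap
  starts <- integer(length(specs))
  occupied <- matrix(integer(0), ncol = 2)
  fixed <- !vapply(specs, function(s) identical(s$insert_position, "random"),
                   logical(1))
  for (i in order(!fixed)) {  # place fixed-position plants first
    ext <- extents[i]
    if (fixed[i]) {
      st <- as.integer(specs[[i]]$insert_position)
      lo <- st - 2L
      if (lo < 1L || lo + ext - 1L > genome_length) {
        stop("plant ", i, " does not fit at its requested position",
             call. = FALSE)
      }
      if (overlaps_any(lo, lo + ext - 1L, occupied)) {
        stop("plants do not fit: requested positions overlap", call. = FALSE)
      }
    } else {
      ok <- FALSE
      for (try in seq_len(500L)) {
        lo <- sample.int(genome_length - ext + 1L, 1L)
        if (lo >= 1L && !overlaps_any(lo, lo + ext - 1L, occupied)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("plants do not fit without overlapping", call. = FALSE)
      st <- lo + 2L
    }
    starts[i] <- st
    occupied <- rbind(occupied, c(st - 2L, st - 2L + ext - 1L))
  }

  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    built <- build_plant(s, bases)
    st <- starts[i]
    seg <- c("A", "A", built$plant, "A", "A")
    g[(st - 2L):(st - 2L + length(seg) - 1L)] <- seg
    truth[[i]] <- tibble::tibble(
      seq_id = seq_id,
      left_start = st,
      left_end = st + s$arm_length - 1L,
      right_start = st + s$arm_length + s$spacer,
      right_end = st + s$arm_length + s$spacer +
        (s$arm_length - s$n_indels) - 1L,
      arm_length = s$arm_length,
      spacer = s$spacer,
      n_substitutions = s$n_substitutions,
      n_indels = s$n_indels,
      arm_gc = s$arm_gc
    )
  }

  residues <- paste(g, collapse = "")
  list(
    sequence = tibble::tibble(seq_id = seq_id, residues = residues,
                              length = genome_length),
    truth = dplyr::bind_rows(truth)
  )
}

#' @keywords internal
overlaps_any <- function(lo, hi, occupied) {
  if (nrow(occupied) == 0L) return(FALSE)
  any(lo <= occupied[, 2] & occupied[, 1] <= hi)
}

# Build the character vector "left arm + spacer + mutated rc(arm)" for one
# spec, using the current RNG stream.
#' @keywords internal
build_plant <- function(s, bases) {
  L <- s$arm_length
  k <- 5L  # defect separation mirrors the default seed size
  gcp <- c((1 - s$arm_gc) / 2, s$arm_gc / 2, s$arm_gc / 2, (1 - s$arm_gc) / 2)
  arm <- sample(bases, L, replace = TRUE, prob = gcp)

  n_def <- s$n_substitutions + s$n_indels
  def_pos <- integer(0)
  if (n_def > 0L) {
    cand <- (k + 1L):(L - k)
    if (length(cand) < n_def) {
      stop("arm too short to hold the requested defects", call. = FALSE)
    }
    def_pos <- pick_separated(cand, n_def, min_gap = k + 1L)
    sub_pos <- def_pos[seq_len(s$n_substitutions)]
    del_pos <- setdiff(def_pos, sub_pos)
    # deletion sites: make the covering triples pairwise distinct so the
    # greedy extension places the gap column exactly at the planted site
    for (t in del_pos) {
      arm[(t - 2L):(t + 2L)] <- c("A", "C", "G", "A", "C")
    }
  } else {
    sub_pos <- integer(0)
    del_pos <- integer(0)
  }

  right <- rev(chartr_vec(arm))  # reverse complement as a vector
  # substitution at left-arm position t hits right-copy index L - t + 1
  for (t in sub_pos) {
    idx <- L - t + 1L
    arm_base <- arm[t]
    choices <- setdiff(bases, chartr("ACGT", "TGCA", arm_base))
    right[idx] <- sample(choices, 1L)
  }
  if (length(del_pos)) {
    right <- right[-(L - del_pos + 1L)]
  }

  spacer_seq <- character(0)
  if (s$spacer > 0L) {
    spacer_seq <- sample(bases, s$spacer, replace = TRUE)
    guard <- seq_len(min(2L, s$spacer))
    spacer_seq[guard] <- "A"
    spacer_seq[s$spacer + 1L - guard] <- "A"
  }
  list(plant = c(arm, spacer_seq, right))
}

#' @keywords internal
chartr_vec <- function(x) {
  strsplit(chartr("ACGT", "TGCA", paste(x, collapse = "")), "")[[1]]
}

# Sample `n` positions from `cand` with pairwise distance >= min_gap;
# falls back to an evenly spaced deterministic layout if rejection fails.
#' @keywords internal
pick_separated <- function(cand, n, min_gap) {
  if (n == 1L) return(cand[sample.int(length(cand), 1L)])
  for (try in seq_len(200L)) {
    pos <- sort(cand[sample.int(length(cand), n)])
    if (all(diff(pos) >= min_gap)) return(pos)
  }
  span <- max(cand) - min(cand)
  if (span < (n - 1L) * min_gap) {
    stop("cannot separate ", n, " defects by ", min_gap, " bp", call. = FALSE)
  }
  as.integer(round(seq(min(cand), max(cand), length.out = n)))
}

#' Exhaustive brute-force search for long inverted repeats
#'
#' The correctness oracle: every pair of disjoint reverse-complementary
#' k-words in the sequence (`k = seed_size`, checked base by base with no
#' window restriction) is grown into its maximal defect-tolerant alignment
#' under the same defect rules as [scan_sequence()] (single mismatches or
#' one-base indels, never two in a row, terminal matches), then filtered by
#' the acceptance thresholds and deduplicated. Implemented independently of
#' the scanner's window sliding and k-mer hashing; quadratic in sequence
#' length, so inputs are capped at 5 kb.
#'
#' @inheritParams scan_sequence
#' @return An LIR tibble with the same columns and ordering as
#'   [scan_sequence()].
#' @export
brute_force_search <- function(seq, params = search_params(), seq_id = NULL) {
  residues <- resolve_residues(seq)
  if (is.null(seq_id)) {
    seq_id <- attr(residues, "seq_id") %||% "seq"
  }
  params <- check_params(params)
  if (nchar(residues) > 5000L) {
    stop("brute_force_search() is quadratic and refuses sequences over ",
         "5 kb; use scan_sequence()", call. = FALSE)
  }
  hits <- brute_force_cpp(residues, params$seed_size, params$min_arm_length,
                          params$max_mismatch_rate, params$min_gc)
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) return(empty_lir_tbl())
  left_length <- hits$left_end - hits$left_start + 1L
  right_length <- hits$right_end - hits$right_start + 1L
  out <- tibble::tibble(
    seq_id = seq_id,
    left_start = hits$left_start, left_end = hits$left_end,
    right_start = hits$right_start, right_end = hits$right_end,
    left_length = left_length, right_length = right_length,
    repeat_length = pmin(left_length, right_length),
    n_defects = hits$n_defects,
    mismatch_rate = hits$mismatch_rate,
    spacer = hits$right_start - hits$left_end - 1L,
    gc = hits$gc,
    alignment = as.character(hits$alignment),
    is_perfect = hits$n_defects == 0L & left_length == right_length
  )
  dplyr::arrange(out, .data$left_start, .data$right_start)
}
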