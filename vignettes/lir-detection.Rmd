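---
title: "Detecting long inverted repeats: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long inverted repeats: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lirscan)
```

## The structure being detected

A long inverted repeat (LIR) is a pair of nearby sequence copies on the
same DNA strand in which one copy is the reverse complement of the other.
In single-stranded DNA or RNA the two copies (the *arms*, or *stem*) can
base-pair with each other and fold into a stem-loop, with the intervening
sequence (the *internal spacer*) forming the loop. Stems longer than about
30 bp are of particular interest: they can induce DNA recombination, are
associated with gene deletion and amplification, and long stable stems in
transcripts can be processed into small RNAs. Arms need not match
perfectly - substitutions and single-base indels between the copies are
common - which is what makes the detection problem hard and what this
package is built around.

An LIR is described by four 1-based inclusive coordinates: the left arm
`left_start..left_end` and the right arm `right_start..right_end`. Derived
quantities are:

* **stem length** `L` (`repeat_length`): the length of the *shorter* arm.
  With indels the two arms differ in length; the shorter arm is what both
  copies can actually pair over, and it is the convention under which the
  bundled reference coordinate set is internally consistent (its rows with
  unequal arms print the shorter length, and their printed mismatch rates
  equal `N / min(arm)` exactly).
* **defects** `N` (`n_defects`): mismatch plus indel columns in the arm
  alignment. Indels are counted together with substitutions; if they were
  free, the mismatch-rate filter could be circumvented by re-describing
  mismatches as paired gaps.
* **mismatch rate** `N / L`, accepted strictly below 0.15 (arm identity
  above 85%).
* **spacer** `right_start - left_end - 1`, always `>= 0`.
* **GC fraction**, computed over the concatenation of both arms, accepted
  strictly above 0.20. This removes low-complexity stems such as `(TA)n`,
  which pair with themselves everywhere. The bound is strict, so a stem
  with GC exactly 0 is rejected even when the threshold is set to 0.
* **delta**: `L / spacer`, the stem-to-spacer ratio; `Inf` for a true
  palindrome (spacer 0).

## Search algorithm

### Seeding

A *seed* is a pair of disjoint exact k-mers (default `k = 5`) in which the
right k-mer is the reverse complement of the left one, both inside one
sliding window (default 2000 bp). Every LIR that passes the acceptance
filters must contain an exact complementary run of at least 5 columns - by
pigeonhole, a stem of length `L >= 15` with fewer than `0.15 L` defects
always has a run of `ceiling((L - N) / (N + 1)) >= 5` matches - so 5-mer
seeding loses nothing at the default thresholds.

Windows advance by half a window (50% overlap), so any repeat whose seeds
span at most half a window is guaranteed to lie fully inside some window;
candidates found in several windows are deduplicated. The original
formulation of this search walks seed-by-seed and re-positions its window
after each hit (re-seeding downstream of the previous spacer, or past the
previous repeat when the spacer is under 5 bp). Enumerating *all* seed
pairs per window subsumes that walk - every pair the walk would visit is
enumerated - and makes the output a deterministic function of the sequence
and parameters, which is what the exhaustive oracle below verifies.
`restart_spacer_threshold` is retained in `search_params()` for interface
completeness.

### Extension

Each seed is extended in both directions, comparing the left-arm cursor
base against the complement of the right-arm cursor base:

* **inward** (toward the loop) until the cursors would meet - the spacer
  never goes negative, and spacer 0 is allowed;
* **outward** without any length limit.

On a failed comparison, three single-column repairs are evaluated: a
substitution (both cursors advance), a gap in the left arm (only the
right cursor advances), or a gap in the right arm (only the left cursor
advances). A repair is accepted *only if the immediately following column
pairs*; this is exactly the rule that two consecutive mismatches or indels
terminate extension, and it guarantees every reported alignment begins and
ends with matched columns and never contains adjacent defect columns.
When several repairs qualify, the substitution is preferred, then the gap
followed by the longer exact run, then the right-arm gap - an arbitrary
but deterministic tie-break. `N` never pairs with anything, so ambiguous
bases can only ever appear inside mismatch columns.

A consequence worth knowing: the greedy repair choice depends on the
direction of traversal. Scanning a sequence and scanning its reverse
complement traverse the same physical alignment in opposite directions,
and in rare shifted-register cases (an alignment overlapping an imperfect
repeat in a different register) a marginal candidate is reachable from one
direction only. The *reported* repeat set is still strand-symmetric in
practice because such by-catch registers are contained inside the true
repeat and removed by redundancy filtering; the package asserts
filtered-set symmetry in its test suite and treats primary-set symmetry as
a diagnostic. An exactly direction-symmetric primary set would require
replacing the greedy extension with an optimal alignment, i.e. a different
method.

### Acceptance filters

A candidate becomes a *primary LIR* when `L >= 30` (inclusive; the
interface treats the configured minimum as attainable), `N / L < 0.15`
and GC `> 0.20`. All three comparisons are strict or inclusive exactly as
stated and are applied identically in the scanner and in the oracle.

## Redundancy removal

Primary lists from repeat-rich sequence contain redundant entries in four
recurring geometries: (A) arms overlapping on one side only, (B) an arm
contained within an arm of another repeat, (C) same-side arms overlapping
with a shift, and (D) one repeat nested entirely inside another's spacer.
For A-C the member with the longer spacer is dropped (ties drop the
shorter stem, then the later start - the published rule does not specify
tie handling, so the package fixes a deterministic one). For D, the two
stems are merged into one reported repeat, represented by the outer stem,
when the same-side arms are within 5 bp *on both sides*; a single-sided
reading would join unrelated stems across arbitrary distances. Nested
stems further apart are genuine distinct structures and both are kept -
the alternative reading (dropping the inner stem as a longer-spacer case)
would discard legitimate nested hairpins. Pairs are re-examined until a
fixpoint is reached, so chains of overlaps resolve regardless of input
order; the operation is idempotent and permutation-invariant, which the
test suite checks property-style.

## Recombinogenicity

Experimentally, inverted repeats separated by short spacers (< 20 bp) with
arm identity above 85% are recombination-prone, and recombinogenic
ability is strong when the stem-to-spacer ratio is large (above ~16). The
classifier combines the three characteristics as follows:

* perfect stem (`N = 0`): recombinogenic iff `delta > 1`, i.e. the loop is
  shorter than the stem (spacer 0 counts, via the `Inf` sentinel);
* imperfect stem: recombinogenic iff `delta >= 100 * N / L`, i.e. delta is
  compared against the mismatch rate *in percent*.

The percent scale is a deliberate calibration decision and the largest
interpretive choice in the package. Compared on a common scale, `delta >=
N / L` would call nearly every detected repeat recombinogenic (any stem
with `delta >= 0.15` would pass, since accepted rates are below 0.15),
which contradicts the reference coordinate set: of its 17 repeats, exactly
2 - both perfect, with spacers of 20 and 14 bp - are recombinogenic, and
rows such as a 32-bp stem with rate 0.031 over a 35-bp spacer
(`delta = 0.91 < 3.1`) are not. The percent-scale reading reproduces all
17 reference calls and is the calibration the package ships
(`is_recombinogenic()`; checked in `tests/testthat/test-acceptance.R`).

```{r classifier}
ref <- lir_reference_coords()
table(called = is_recombinogenic(ref$repeat_length, ref$mismatch_rate,
                                 ref$spacer),
      reference = ref$recombinogenic)
```

One reference-set footnote: the last row prints a spacer of 811 while its
own printed coordinates give `3990425 - 3989614 - 1 = 810`. The other 16
rows pin the spacer convention exactly, so this is a typo in the printed
table; the fixture ships the values as printed and the corresponding
arithmetic check deliberately flags that single row rather than masking
it.

## The synthetic-data generator and the oracle

`plant_lirs()` writes known repeats into an i.i.d. uniform A/C/G/T
background (GC 0.5 by default, so the GC filter is never triggered by the
background; the arm GC is settable for filter tests). Design points:

* Two guard bases (`A`) flank each plant and cap each spacer end. Guards
  on both sides can never pair with each other (`A` against `A`), and all
  repair lookaheads across the boundary fail too, so neither inward nor
  outward extension can creep past the planted coordinates by chance -
  planted truth is exact, not approximate, and recall is asserted at
  exact coordinates.
* Defects are placed in the arm interior with pairwise separation greater
  than the seed size. This is a fairness condition of the *recall
  property*, not of the tool: a plant whose defects are adjacent is
  undiscoverable by construction of the defect rules, and a plant with
  defects denser than one per seed length may lose every clean seed.
* Around a planted deletion the arm is locally recoded so the three bases
  spanning the site are pairwise distinct; otherwise a deletion inside a
  homopolymer is positionally ambiguous and the greedy extension may place
  the gap column at a neighbouring offset (the classic indel
  left/right-alignment ambiguity).

What the generator does not emulate: repeat families, transposons,
isochore GC structure, or any long-range correlation of real genomes.
Passing recall and equivalence tests on these fixtures demonstrates the
algorithm's correctness under its own model, not field performance on a
primate chromosome.

`brute_force_search()` is the correctness oracle: it enumerates *every*
disjoint reverse-complementary k-word pair (checked base by base, no
window machinery, no k-mer hashing) and extends each with an independently
written implementation of the same defect rules, then filters and
deduplicates. On sequences up to one window long - where windowing cannot
matter - the scanner and the oracle must agree exactly, and the test suite
asserts identity of the full candidate sets (coordinates, defect counts
and alignment strings) over 100 seeded random 1-2 kb sequences under two
parameter settings. The oracle is quadratic and refuses inputs over 5 kb.
Anchor enumeration deliberately starts from seed words rather than single
complementary base pairs: because greedy repair is direction-dependent,
single-column anchoring reaches alignment variants whose exact runs are
all shorter than one seed, which no seeded scanner can produce - the
seed-word anchor set is the correct model of the search being verified.

## Degenerate inputs and numerical conventions

* Sequences shorter than two minimum arms return an empty result.
* IUPAC ambiguity codes other than `N` are mapped to `N` on input (with a
  warning); `N` never pairs and never seeds.
* `gc_fraction()` excludes `N` from its denominator and returns `NA` for
  all-`N` input; an arm consisting only of `N` cannot arise because arms
  terminate in matched columns.
* Mismatch rates are *printed* truncated to three decimals in the TSV
  report, matching the convention of the reference table (0.0566 prints
  as 0.056); the stored values are exact.
* BED output is 0-based half-open with the left arm on `+` and the right
  arm on `-`; the TSV keeps 1-based inclusive coordinates throughout.

## Problem sizes

The shipped tests and the acceptance script use fixture sizes chosen to
exercise every code path at desk scale: 100 random sequences of 1-2 kb
for scanner/oracle equivalence, 50 genomes of 10 kb with three planted
repeats each (arms 30-80 bp, spacers 0-500 bp, 0-3 well-separated
substitutions) for recall, ten 8-kb two-plant fixtures for strand
symmetry, and one 20-kb six-plant genome for the end-to-end demonstration.
A full-scale benchmark against the 7.1 Mb human chromosome 4 contig
NT_022853.16 - whose published run reports 1443 primary repeats, 28 of
them perfect, 656 after filtering and 4 recombinogenic - is provided as
`scripts/benchmark_nt022853.R`; it requires downloading the contig and
records the package's own counts beside the reference values, with exact
agreement explicitly not guaranteed given the documented interpretive
choices in the extension and merge rules.

## Known limitations

* The extension is greedy with one-column lookahead, per the method it
  implements; it does not compute optimal (minimum-defect) alignments,
  and primary-set strand symmetry is only approximate (see above).
* The scanner is pure R orchestration over a C++ extension kernel; a
  multi-megabase contig takes tens of minutes on one core. No suffix
  array / FM-index acceleration is attempted.
* Arms longer than one window are not findable by construction (both
  seeds must share a window), matching the windowed definition of the
  search.
* The recombinogenicity call is a binary geometric classifier, not a
  mechanistic or quantitative model of recombination rates.
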