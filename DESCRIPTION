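Package: lirscan
Title: Detection of Long Inverted Repeats in DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds long inverted repeats (LIRs) - pairs of nearby
    reverse-complementary sequence copies that can fold into stem-loop
    structures - in DNA sequences. Implements an exhaustive seed-and-extend
    search with mismatch- and indel-tolerant bidirectional extension,
    GC-content and mismatch-rate acceptance filters, removal of redundant
    overlapping repeats, and a recombinogenicity classifier based on the
    ratio of stem length to internal spacer. Includes a synthetic-genome
    generator with planted repeats and an exhaustive brute-force finder used
    as a correctness oracle, plus TSV and BED report writers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stringi,
    Rcpp,
    stringr,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
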