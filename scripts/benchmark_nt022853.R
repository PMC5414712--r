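#!/usr/bin/env Rscript

# Optional genome-scale benchmark on human chromosome 4 contig
# NT_022853.16 (7,084,842 bp). The contig is not bundled (it is far too
# large for the repository); download it once, e.g.:
#
#   efetch -db nucleotide -id NT_022853.16 -format fasta > NT_022853.16.fa
#
# or fetch the same accession from NCBI in a browser, then run:
#
#   Rscript scripts/benchmark_nt022853.R NT_022853.16.fa [out_prefix]
#
# With default settings (window 2000 bp, minimum stem 30 bp, seed 5 bp)
# the published reference run of this search reports 1443 primary LIRs
# (28 perfect, 1415 imperfect), 656 after redundancy filtering, and 4
# recombinogenic. This script records the package's own counts next to
# those reference values; the extension and merge rules involve documented
# interpretive choices, so exact agreement is not guaranteed. Expect a
# runtime of tens of minutes on one core.

suppressPackageStartupMessages(library(lirscan))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/benchmark_nt022853.R <contig.fa> [out_prefix]")
}
fasta <- args[1]
prefix <- if (length(args) >= 2) args[2] else "nt022853_benchmark"

t0 <- Sys.time()
res <- run_lir_scan(fasta, prefix, emit_bed = TRUE, quiet = FALSE)
elapsed <- difftime(Sys.time(), t0, units = "mins")

s <- glance(res)
reference <- c(primary = 1443, perfect = 28, imperfect = 1415,
               filtered = 656, recombinogenic = 4)
observed <- c(primary = s$n_primary, perfect = s$n_perfect,
              imperfect = s$n_imperfect, filtered = s$n_filtered,
              recombinogenic = s$n_recombinogenic)
report <- data.frame(quantity = names(reference),
                     reference = as.integer(reference),
                     observed = as.integer(observed))
write.table(report, paste0(prefix, "_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report)
cat(sprintf("elapsed: %.1f min\n", as.numeric(elapsed)))
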