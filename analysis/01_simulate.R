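#!/usr/bin/env Rscript
# Build the eight-taxon synthetic comparative panel under the default study
# conditions (~150 kb quadripartite plastomes, conserved rps19/ndhF/ycf1
# junction layout, planted SSRs, shared A/T-biased codon profile; the last
# taxon carries a flipped alanine-family codon profile as an SVC marker).
# Emits one GenBank flat file + ground-truth JSON sidecar per taxon.

suppressMessages(library(plastomics))

seed <- 20260920L
out_dir <- "results/panel"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

panel <- build_comparative_panel(seed)
for (tx in names(panel)) {
  paths <- write_synthetic(panel[[tx]], out_dir)
  message(sprintf("%s: %s bp, %d features -> %s", tx,
                  format(genome_length(panel[[tx]]$record), big.mark = ","),
                  length(panel[[tx]]$record$features), paths[1]))
}
message(sprintf("panel of %d taxa written to %s (seed %d)",
                length(panel), out_dir, seed))
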