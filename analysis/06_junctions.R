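#!/usr/bin/env Rscript
# IR junction analysis across the panel: gene placements at JLB/JSB/JSA/JLA,
# the rps19-into-IRb extension diagnostic, and the truncated-ycf1/ndhF
# overlap at the IRb/SSC boundary.

suppressMessages(library(plastomics))

gb <- list.files("results/panel", pattern = "\\.gb$", full.names = TRUE)
stopifnot(length(gb) > 0)
dir.create("results/junctions", showWarnings = FALSE, recursive = TRUE)

recs <- lapply(gb, function(p) read_genbank(p)[[1]])
reports <- list(); overlaps <- numeric(0)
for (rec in recs) {
  part <- detect_partition(rec)
  reports[[rec$id]] <- junction_report(rec, part)
  overlaps[rec$id] <- gene_overlap(rec, "ycf1", "ndhF",
                                   pseudo_a = TRUE, pseudo_b = FALSE)
}

cmp <- compare_junctions(reports, diagnostics = list(
  rps19_in_irb_100bp = list(gene = "rps19", junction = "JLB", min_extension = 100L),
  ndhf_reaches_irb = list(gene = "ndhF", junction = "JSB", min_extension = 1L)))
write.table(cmp$table, "results/junctions/placements.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(taxon = rownames(cmp$diagnostics), cmp$diagnostics),
            "results/junctions/diagnostics.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(taxon = names(overlaps), ycf1_pseudo_ndhf_overlap_bp = overlaps),
            "results/junctions/ycf1_ndhf_overlap.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

ext <- cmp$table[cmp$table$gene == "rps19" & cmp$table$placement == "spans" &
                   !cmp$table$pseudo, c("taxon", "bp_left", "bp_right")]
print(ext)
message("rps19 IRb extension conserved at ", unique(ext$bp_right),
        " bp in all taxa: ", length(unique(ext$bp_right)) == 1)
message("truncated-ycf1/ndhF overlaps (bp): ",
        paste(unique(overlaps), collapse = " "))
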