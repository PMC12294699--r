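#!/usr/bin/env Rscript
# Codon usage across the panel: RSCU tables, amino-acid frequencies, start
# codon audit, and the cross-taxon SVC comparison that singles out the
# marker taxon.

suppressMessages(library(plastomics))

gb <- list.files("results/panel", pattern = "\\.gb$", full.names = TRUE)
stopifnot(length(gb) > 0)
dir.create("results/codon_usage", showWarnings = FALSE, recursive = TRUE)

recs <- lapply(gb, function(p) read_genbank(p)[[1]])
tabs <- lapply(recs, function(r)
  rscu(suppressWarnings(count_codons(r, dedupe_ir = TRUE))))

write.table(rscu_table(tabs), "results/codon_usage/rscu.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

aa <- do.call(rbind, lapply(tabs, function(tb)
  data.frame(taxon = tb$taxon, t(round(tb$aa_freq, 4)))))
write.table(aa, "results/codon_usage/aa_frequencies.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("most abundant amino acid per taxon: ",
        paste(unique(apply(aa[, -1], 1, function(x) names(aa)[-1][which.max(x)])),
              collapse = ", "))

starts <- do.call(rbind, lapply(recs, function(r) {
  inv <- start_codon_inventory(r)
  if (length(inv$non_atg) == 0) return(NULL)
  data.frame(taxon = r$id, gene = names(inv$non_atg),
             start_codon = unname(inv$non_atg))
}))
if (!is.null(starts))
  write.table(starts, "results/codon_usage/non_atg_starts.tsv",
              sep = "\t", row.names = FALSE, quote = FALSE)

svc <- find_svcs(tabs)
excl <- svc_exclusive_counts(svc)
svc_tab <- data.frame(codon = svc$svc_codons,
                      minority_taxa = vapply(svc$exclusivity, function(e)
                        paste(e$taxa, collapse = ","), character(1)))
write.table(svc_tab, "results/codon_usage/svc.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message(sprintf("%d SVCs found; exclusive counts: %s",
                length(svc$svc_codons),
                paste(sprintf("%s=%d", names(excl)[excl > 0], excl[excl > 0]),
                      collapse = " ")))
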