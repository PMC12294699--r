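#!/usr/bin/env Rscript
# Microsatellite scan with one IR copy removed, per-locus tables and the
# type/region summaries, validated against each genome's planted set.

suppressMessages(library(plastomics))

gb <- list.files("results/panel", pattern = "\\.gb$", full.names = TRUE)
truths <- list.files("results/panel", pattern = "\\.truth\\.json$", full.names = TRUE)
stopifnot(length(gb) > 0)
dir.create("results/ssr", showWarnings = FALSE, recursive = TRUE)

summary_rows <- list()
for (p in gb) {
  rec <- read_genbank(p)[[1]]
  part <- detect_partition(rec)
  sc <- scan_plastome_ssrs(rec, part)
  write.table(sc$loci, file.path("results/ssr", paste0(rec$id, "_loci.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  tj <- jsonlite::read_json(file.path("results/panel",
                                      paste0(rec$id, ".truth.json")),
                            simplifyVector = TRUE)
  planted <- tj$ssrs_linearized
  recovered <- nrow(sc$loci) == nrow(planted) &&
    all(sort(sc$loci$start) == sort(planted$start))
  summary_rows[[rec$id]] <- data.frame(
    taxon = rec$id, total = sc$summary$total,
    mono = unname(sc$summary$by_unit_len["1"]),
    di = unname(sc$summary$by_unit_len["2"]),
    mono_share_pct = round(100 * sc$summary$by_unit_len["1"] / sc$summary$total, 1),
    lsc = unname(sc$summary$by_region["LSC"]),
    irb = unname(sc$summary$by_region["IRb"]),
    ssc = unname(sc$summary$by_region["SSC"]),
    planted_recovered = recovered, stringsAsFactors = FALSE)
}
tab <- do.call(rbind, summary_rows)
write.table(tab, "results/ssr/summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab)
message("planted SSR sets recovered exactly in all taxa: ",
        all(tab$planted_recovered))
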