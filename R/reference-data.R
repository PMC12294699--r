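# Published reference statistics shipped with the package.

#' Published genome statistics for eight Sedum plastomes
#'
#' Reported whole-genome summary statistics for the eight Sedum plastomes
#' deposited under GenBank accessions PV751241-PV751248: total and
#' per-region lengths, base percentages and AT/GC skews. These serve as
#' desk-check inputs: the skews must be recomputable from the base
#' percentages (see [composition()]) and the region lengths must satisfy
#' the quadripartite identity LSC + SSC + 2 x IR = genome size.
#'
#' @return data.frame, one row per species.
#' @export
sedum_reference_stats <- function() {
  path <- system.file("extdata", "sedum_plastome_stats.tsv",
                      package = "plastomics", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
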