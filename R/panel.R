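# A ready-made comparative panel emulating an eight-species plastome study.

#' Build a synthetic eight-taxon comparative panel
#'
#' Generates `n_taxa` full-size synthetic plastomes under the default study
#' conditions ([plastome_spec()] defaults: ~150 kb quadripartite genomes,
#' the conserved rps19/ndhF/ycf1 junction layout, planted SSRs, a shared
#' A/T-biased codon profile). When `marker_taxon` is `TRUE`, the last taxon
#' carries a codon-profile edit that flips the alanine-family preference
#' (GCT depressed, GCC boosted), creating codons exclusive to that taxon in
#' cross-taxon SVC comparisons -- the single-species marker situation seen
#' in real plastome panels.
#'
#' @param seed integer; taxon i draws from `seed * 100 + i`.
#' @param n_taxa number of taxa (default 8).
#' @param marker_taxon give the last taxon the flipped codon profile.
#' @param base optionally override the base [plastome_spec()].
#' @return named list: taxon -> list(record, truth), as [make_taxon_set()].
#' @export
build_comparative_panel <- function(seed, n_taxa = 8L, marker_taxon = TRUE,
                                    base = plastome_spec()) {
  stopifnot(n_taxa >= 2L)
  flipped <- base$cds_profile
  flipped["GCT"] <- flipped["GCT"] * 0.05
  flipped["GCC"] <- flipped["GCC"] * 8
  edits <- stats::setNames(
    lapply(seq_len(n_taxa), function(i) {
      e <- list(seed = as.integer(seed) * 100L + i)
      if (marker_taxon && i == n_taxa) e$cds_profile <- flipped
      e
    }),
    sprintf("taxon%02d", seq_len(n_taxa)))
  make_taxon_set(base, edits)
}
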