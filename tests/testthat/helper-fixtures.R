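# Shared fixtures built in code.

# a small spec with the conserved junction layout scaled down:
# rps19 with 110 bp inside IRb, ndhF reaching `ndhf_in_irb` bp into the IRb,
# ycf1 spanning JSA (mirror = the truncated ycf1 copy)
small_spec <- function(seed, lsc = 2000L, ssc = 700L, ir = 450L,
                       ndhf_in_irb = 40L, n_cds = 2L,
                       ssrs = data.frame(motif = "A", repeats = 9L,
                                         region = "LSC", offset = 400L,
                                         stringsAsFactors = FALSE)) {
  plastome_spec(
    lsc_len = lsc, ssc_len = ssc, ir_len = ir,
    junction_genes = data.frame(
      name = c("rps19", "ndhF", "ycf1"),
      junction = c("JLB", "JSB", "JSA"),
      bp_upstream = c(169L, ndhf_in_irb, 99L),
      bp_downstream = c(110L, 200L, 150L),
      strand = c("-", "-", "+"), pseudo = FALSE, stringsAsFactors = FALSE),
    planted_ssrs = ssrs,
    n_cds = n_cds, cds_len_range = c(60L, 120L), n_cds_ir = 0L, seed = seed)
}

# hand-built record: one explicit sequence and feature list
toy_record <- function(seq, features = list(), id = "toy", circular = TRUE) {
  plastome_record(id, seq, circular, features)
}

# random codon usage table (counts drawn per family), RSCU filled
random_codon_table <- function(taxon, seed) {
  set.seed(seed)
  counts <- setNames(rpois(64, lambda = sample(c(0, 2, 20), 64, replace = TRUE,
                                               prob = c(.15, .35, .5))),
                     plastomics:::all_codons())
  tb <- structure(list(taxon = taxon, counts = counts, rscu = NULL,
                       aa_freq = NULL, start_codons = NULL),
                  class = "codon_usage_table")
  rscu(tb)
}

# minimal GenBank text written to a temp file, returned as path
write_gb_text <- function(lines) {
  p <- tempfile(fileext = ".gb")
  writeLines(lines, p)
  p
}
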