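test_that("genome length is the sum of the four regions", {
  sp <- plastome_spec(lsc_len = 2000L, ssc_len = 600L, ir_len = 400L,
                      junction_genes = default_junction_genes()[0, ],
                      planted_ssrs = default_planted_ssrs()[0, ],
                      n_cds = 2L, cds_len_range = c(60L, 90L), n_cds_ir = 0L,
                      seed = 1)
  res <- make_plastome(sp)
  expect_equal(genome_length(res$record), 3400L)
  expect_equal(res$truth$partition$length, 3400L)
})

test_that("output is byte-identical for identical spec and seed", {
  a <- make_plastome(small_spec(77))
  b <- make_plastome(small_spec(77))
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$truth, b$truth)
  c <- make_plastome(small_spec(78))
  expect_false(identical(a$record$seq, c$record$seq))
})

test_that("the IRb is the exact reverse complement of the IRa by construction", {
  res <- make_plastome(small_spec(81))
  tr <- res$truth$partition
  irb <- substr(res$record$seq, tr$lsc_len + 1L, tr$lsc_len + tr$ir_len)
  ira <- substr(res$record$seq, tr$length - tr$ir_len + 1L, tr$length)
  expect_identical(irb, plastomics::revcomp(ira))
})

test_that("infeasible specifications error before any output", {
  expect_error(plastome_spec(lsc_len = 500L, ssc_len = 600L, ir_len = 200L),
               "lsc_len")
  expect_error(
    plastome_spec(planted_ssrs = data.frame(
      motif = "A", repeats = 7L, region = "LSC", offset = 100L)),
    "threshold")
  expect_error(
    plastome_spec(planted_ssrs = data.frame(
      motif = "ATAT", repeats = 3L, region = "LSC", offset = 100L)),
    "primitive")
  expect_error(
    plastome_spec(lsc_len = 2000L, ssc_len = 500L, ir_len = 300L,
                  junction_genes = data.frame(
                    name = "huge", junction = "JLB", bp_upstream = 100L,
                    bp_downstream = 400L, strand = "+", pseudo = FALSE)),
    "fit")
  # overlapping planted content is refused at generation time
  sp <- small_spec(9, ssrs = data.frame(
    motif = "A", repeats = 9L, region = "IRb", offset = 50L,  # inside rps19 arm
    stringsAsFactors = FALSE))
  expect_error(make_plastome(sp), "overlaps")
})

test_that("realized codon counts match the emitted coding sequences", {
  res <- make_plastome(small_spec(92))
  counts <- unlist(res$truth$codon_counts)
  redo <- suppressWarnings(
    codon_table_from_seqs(cds_sequences(res$record), "x"))$counts
  expect_equal(counts, redo)
})

test_that("sampled codon frequencies track the profile within multinomial error", {
  sp <- plastome_spec(lsc_len = 30000L, ssc_len = 2000L, ir_len = 1000L,
                      junction_genes = default_junction_genes()[0, ],
                      planted_ssrs = default_planted_ssrs()[0, ],
                      n_cds = 30L, cds_len_range = c(200L, 300L),
                      n_cds_ir = 0L, seed = 15)
  res <- make_plastome(sp)
  counts <- unlist(res$truth$codon_counts)
  prof <- sp$cds_profile
  sense <- names(prof)
  n_body <- sum(counts[sense]) - sum(counts[c("ATG")]) + 0  # ATG also in bodies
  obs <- counts[sense] / sum(counts[sense])
  # repairs perturb a handful of codons; 3 percentage points is generous
  expect_lt(max(abs(obs - prof)), 0.03)
  # and the taxon-level comparison survives the round trip through RSCU
  tb <- rscu(suppressWarnings(count_codons(res$record)))
  third <- substr(sense, 3, 3)
  at_end <- tb$rscu[sense][third %in% c("A", "T")]
  gc_end <- tb$rscu[sense][!third %in% c("A", "T")]
  expect_gt(mean(at_end > 1, na.rm = TRUE), 0.9)   # A/T-ending preferred
  expect_gt(mean(gc_end <= 1, na.rm = TRUE), 0.9)
})

test_that("taxon panels apply per-taxon edits with distinct seeds", {
  base <- small_spec(500)
  flipped <- default_codon_profile()
  # depress GCT, boost GCC: flips the Ala family pattern in one taxon
  flipped["GCT"] <- flipped["GCT"] * 0.05
  flipped["GCC"] <- flipped["GCC"] * 8
  panel <- make_taxon_set(base, list(
    tax1 = list(), tax2 = list(), tax3 = list(cds_profile = flipped)))
  expect_named(panel, c("tax1", "tax2", "tax3"))
  expect_false(identical(panel$tax1$record$seq, panel$tax2$record$seq))
  tabs <- lapply(panel, function(x)
    rscu(suppressWarnings(count_codons(x$record, dedupe_ir = TRUE))))
  rep <- find_svcs(unname(tabs))
  expect_true("GCT" %in% rep$svc_codons)
  expect_equal(rep$exclusivity[["GCT"]]$taxa, "tax3")
})

test_that("synthetic output round-trips through GenBank + JSON sidecar", {
  res <- make_plastome(small_spec(601))
  dir <- tempfile()
  paths <- write_synthetic(res, dir)
  rec2 <- read_genbank(paths[1])[[1]]
  expect_identical(rec2$seq, res$record$seq)
  truth2 <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(truth2$partition$lsc_len, res$truth$partition$lsc_len)
  expect_equal(truth2$seed, res$truth$seed)
})
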