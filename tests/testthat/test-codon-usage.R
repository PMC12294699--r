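test_that("codon counting handles strands, stops and warnings", {
  # plus-strand CDS counted directly, stop separate
  rec <- toy_record(paste0("ATGCTTCTTCTATAA", strrep("G", 35)),
                    list(gene_feature("g1", "PCG", list(interval(0, 15)))))
  tb <- count_codons(rec)
  expect_equal(unname(tb$counts[c("ATG", "CTT", "CTA", "TAA")]), c(1L, 2L, 1L, 1L))

  # minus-strand CDS: top strand holds the reverse complement
  top <- plastomics::revcomp("ATGAAATAA")
  rec2 <- toy_record(paste0(strrep("C", 20), top, strrep("G", 21)),
                     list(gene_feature("g2", "PCG",
                                       list(interval(20, 29, "-")))))
  tb2 <- count_codons(rec2)
  expect_equal(unname(tb2$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))

  # length not divisible by 3 -> excluded with warning; none left -> error
  rec3 <- toy_record(strrep("A", 40),
                     list(gene_feature("g3", "PCG", list(interval(0, 10)))))
  expect_warning(expect_error(count_codons(rec3), "no qualifying CDS"),
                 "not divisible")

  # internal stop warns and names the gene
  rec4 <- toy_record(paste0("ATGTAACTATAA", strrep("G", 28)),
                     list(gene_feature("g4", "PCG", list(interval(0, 12)))))
  expect_warning(count_codons(rec4), "g4")
})

test_that("RSCU follows the family-mean definition", {
  counts <- setNames(integer(64), plastomics:::all_codons())
  counts["CTT"] <- 2L; counts["CTA"] <- 1L
  tb <- structure(list(taxon = "t", counts = counts, rscu = NULL),
                  class = "codon_usage_table")
  r <- rscu(tb)$rscu
  expect_equal(r[["CTT"]], 4)    # Leu family size 6, mean 0.5
  expect_equal(r[["CTA"]], 2)
  expect_equal(r[["TTA"]], 0)
  expect_true(is.na(r[["GCT"]])) # empty family: missing, not 0
  expect_true(is.na(r[["TAA"]])) # stops carry no RSCU

  counts2 <- counts; counts2[] <- 0L; counts2["ATG"] <- 5L
  r2 <- rscu(structure(list(taxon = "t", counts = counts2, rscu = NULL),
                       class = "codon_usage_table"))$rscu
  expect_equal(r2[["ATG"]], 1)   # single-codon family

  counts3 <- setNames(rep(7L, 64), plastomics:::all_codons())
  r3 <- rscu(structure(list(taxon = "t", counts = counts3, rscu = NULL),
                       class = "codon_usage_table"))$rscu
  expect_true(all(abs(r3[!is.na(r3)] - 1) < 1e-12))  # uniform counts
})

test_that("RSCU family sums equal family size and are scale invariant", {
  code <- plastomics:::.plastid_code()
  fams <- split(names(code), unname(code))
  for (seed in 1:10) {
    tb <- random_codon_table("t", seed)
    for (fam in fams) {
      if (code[[fam[1]]] == "*") next
      vals <- tb$rscu[fam]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fam), tolerance = 1e-12)
    }
    tb10 <- tb; tb10$counts <- tb$counts * 10L
    expect_equal(rscu(tb10)$rscu, tb$rscu)
  }
})

test_that("SVC classification matches its definition and the exhaustive oracle", {
  mk <- function(taxon, edits) {
    counts <- setNames(rep(10L, 64), plastomics:::all_codons())
    for (cd in names(edits)) counts[cd] <- edits[[cd]]
    rscu(structure(list(taxon = taxon, counts = counts, rscu = NULL),
                   class = "codon_usage_table"))
  }
  # GCT preferred in one taxon, unpreferred in the other -> SVC
  t1 <- mk("tx1", list(GCT = 30L))   # GCT RSCU > 1
  t2 <- mk("tx2", list(GCA = 30L))   # GCT RSCU < 1
  rep2 <- find_svcs(list(t1, t2))
  expect_true("GCT" %in% rep2$svc_codons)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% rep2$svc_codons))

  # identical tables -> no SVC
  expect_length(find_svcs(list(t1, mk("tx2", list(GCT = 30L))))$svc_codons, 0L)
  expect_error(find_svcs(list(t1)), "two taxa")

  # oracle equivalence on random panels of up to 10 taxa
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(2:10, 1)
    tabs <- lapply(seq_len(n), function(i) random_codon_table(paste0("t", i), seed * 100 + i))
    expect_identical(sort(find_svcs(tabs)$svc_codons), oracle_svcs(tabs))
  }
})

test_that("SVC exclusivity identifies the minority taxon", {
  mk <- function(taxon, gct) {
    counts <- setNames(rep(10L, 64), plastomics:::all_codons())
    counts["GCT"] <- gct
    rscu(structure(list(taxon = taxon, counts = counts, rscu = NULL),
                   class = "codon_usage_table"))
  }
  tabs <- c(lapply(1:7, function(i) mk(paste0("maj", i), 30L)),
            list(mk("odd", 2L)))
  rep <- find_svcs(tabs)
  # depressing GCT raises the rest of the Ala family above 1 in the odd
  # taxon, so all four Ala codons flip class there and nowhere else
  expect_setequal(rep$svc_codons, c("GCT", "GCC", "GCA", "GCG"))
  expect_equal(rep$exclusivity[["GCT"]]$taxa, "odd")
  ex <- svc_exclusive_counts(rep)
  expect_equal(unname(ex[["odd"]]), 4L)
  expect_true(all(ex[names(ex) != "odd"] == 0L))
})

test_that("start codons are audited, alternative initiators flagged", {
  rec <- toy_record(paste0("ATGAAATAA", "GTGCCCTAG", strrep("C", 22)),
                    list(gene_feature("gA", "PCG", list(interval(0, 9))),
                         gene_feature("ndhD", "PCG", list(interval(9, 18)))))
  inv <- start_codon_inventory(rec)
  expect_equal(unname(inv$starts[["gA"]]), "ATG")
  expect_equal(names(inv$non_atg), "ndhD")
  expect_equal(unname(inv$non_atg[["ndhD"]]), "GTG")
})

test_that("amino-acid frequencies sum to one and recover a Leu-rich profile", {
  set.seed(3)
  prof <- default_codon_profile()
  body <- sample(names(prof), 4000, replace = TRUE, prob = prof)
  cds <- paste0("ATG", paste0(body, collapse = ""), "TAA")
  tb <- codon_table_from_seqs(c(gene = cds))
  expect_equal(sum(tb$aa_freq), 1)
  expect_equal(names(which.max(tb$aa_freq)), "L")
  expect_equal(names(which.min(tb$aa_freq)), "C")
})

test_that("IR-duplicated genes are counted once only under dedupe", {
  res <- make_plastome(plastome_spec(
    lsc_len = 2500L, ssc_len = 700L, ir_len = 500L,
    junction_genes = default_junction_genes()[0, ],
    planted_ssrs = default_planted_ssrs()[0, ],
    n_cds = 2L, cds_len_range = c(60L, 90L), n_cds_ir = 1L, seed = 19))
  both <- count_codons(res$record, dedupe_ir = FALSE)
  once <- count_codons(res$record, dedupe_ir = TRUE)
  expect_equal(sum(both$counts) - sum(once$counts),
               sum(once$counts[once$counts > 0] * 0) +
                 sum(both$counts - once$counts))
  expect_gt(sum(both$counts), sum(once$counts))
  # the duplicated gene contributes exactly its own codons twice
  irx <- Filter(function(f) grepl("^irx", f$name), res$record$features)
  irx_len <- interval_length(irx[[1]]$parts[[1]])
  expect_equal(sum(both$counts) - sum(once$counts), irx_len / 3)
})
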