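mk_rec <- function(id, genes, L = 400L) {
  # genes: named list gene -> c(start, len) or list(start, len, pseudo)
  feats <- lapply(names(genes), function(g) {
    v <- genes[[g]]
    ps <- if (is.list(v)) isTRUE(v$pseudo) else FALSE
    gene_feature(g, "PCG", list(interval(v[[1]], v[[1]] + v[[2]])), pseudo = ps)
  })
  plastome_record(id, strrep("ATGAAATAAC", L / 10), TRUE, feats)
}

test_that("the shared gene set is the intersection with exclusions recorded", {
  r1 <- mk_rec("tx1", list(a = c(0L, 30L), b = c(40L, 30L), c = c(80L, 30L)))
  r2 <- mk_rec("tx2", list(a = c(0L, 30L), c = c(80L, 30L)))
  r3 <- mk_rec("tx3", list(a = c(0L, 30L), c = c(80L, 30L), d = c(120L, 30L)))
  sel <- select_shared_pcgs(list(r1, r2, r3))
  expect_equal(sel$shared_genes, c("a", "c"))

  # pseudo in one taxon: dropped from the shared set with a reason
  r2b <- mk_rec("tx2", list(a = c(0L, 30L), c = list(80L, 30L, pseudo = TRUE)))
  sel2 <- select_shared_pcgs(list(r1, r2b, r3))
  expect_equal(sel2$shared_genes, "a")
  expect_true(any(sel2$exclusions$gene == "c" &
                    sel2$exclusions$reason == "pseudo/absent"))

  # length not a codon multiple: excluded per-taxon
  r2c <- mk_rec("tx2", list(a = c(0L, 30L), c = c(80L, 31L)))
  sel3 <- select_shared_pcgs(list(r1, r2c))
  expect_equal(sel3$shared_genes, "a")
  expect_true(any(sel3$exclusions$reason == "length not a codon multiple"))

  expect_error(select_shared_pcgs(list(r1)), "two records")
  rx <- mk_rec("tx4", list(zz = c(0L, 30L)))
  expect_error(select_shared_pcgs(list(r1, rx)), "shared")
})

test_that("IR duplicates collapse to the longest copy", {
  r <- mk_rec("tx", list(a = c(0L, 30L)))
  r$features <- c(r$features,
                  list(gene_feature("a", "PCG", list(interval(100, 160))),
                       gene_feature("b", "PCG", list(interval(200, 230)))))
  r2 <- mk_rec("ty", list(a = c(0L, 30L), b = c(40L, 30L)))
  sel <- select_shared_pcgs(list(r, r2))
  expect_equal(sel$shared_genes, c("a", "b"))
  # the 60 bp copy (index 2 in the feature list) wins
  expect_equal(unname(sel$representatives[["tx"]][["a"]]), 2L)
})

test_that("concatenation tiles partitions and matches rows by taxon label", {
  g1 <- c(tx1 = "ATGAAA", tx2 = "ATG--A")
  g2 <- c(tx2 = "CCCGGGTTT", tx1 = "CCC---TTT")   # shuffled taxon order
  sm <- concatenate_alignments(list(a = g1, b = g2))
  expect_equal(sm$total_length, 15L)
  expect_equal(sm$partitions$start, c(1L, 7L))
  expect_equal(sm$partitions$end, c(6L, 15L))
  expect_equal(unname(sm$matrix[["tx2"]]), "ATG--ACCCGGGTTT")

  # single gene: the supermatrix is that alignment
  sm1 <- concatenate_alignments(list(a = g1))
  expect_equal(unname(sm1$matrix[sm1$taxa]), unname(g1[sm1$taxa]))

  expect_error(concatenate_alignments(list(a = c(tx1 = "AAA", tx2 = "AAAA"))),
               "ragged")
  expect_error(concatenate_alignments(list(a = g1, b = c(tx1 = "AAA", tx9 = "AAA"))),
               "mismatch")
})

test_that("partition ranges slice each gene back out and residues are conserved", {
  set.seed(91)
  genes <- list()
  taxa <- c("s1", "s2", "s3")
  for (g in c("ga", "gb", "gc")) {
    len <- sample(c(6L, 9L, 12L), 1)
    al <- vapply(taxa, function(t) {
      s <- strsplit(random_dna(len), "")[[1]]
      s[sample(len, sample(0:2, 1))] <- "-"
      paste0(s, collapse = "")
    }, character(1))
    genes[[g]] <- al
  }
  sm <- concatenate_alignments(genes)
  for (i in seq_len(nrow(sm$partitions))) {
    gene <- sm$partitions$gene[i]
    for (t in taxa) {
      expect_equal(substr(sm$matrix[[t]], sm$partitions$start[i],
                          sm$partitions$end[i]),
                   unname(genes[[gene]][[t]]))
    }
  }
  for (t in taxa) {
    all_res <- sort(strsplit(gsub("-", "", sm$matrix[[t]]), "")[[1]])
    per_gene <- sort(unlist(strsplit(gsub("-", "", vapply(genes, `[[`, character(1), t)), "")))
    expect_equal(all_res, unname(per_gene))
  }
})

test_that("supermatrix and per-gene exports round-trip through disk", {
  res1 <- make_plastome(small_spec(401)); res1$record$id <- "taxA"
  res2 <- make_plastome(small_spec(402)); res2$record$id <- "taxB"
  recs <- list(res1$record, res2$record)
  sel <- select_shared_pcgs(recs)
  expect_true(all(c("rps19", "ndhf", "ycf1") %in% sel$shared_genes))
  dir <- tempfile(); paths <- export_gene_fastas(recs, sel, dir)
  # junction genes have fixed lengths across taxa, so their unaligned
  # exports already form equal-length rows
  keep <- list.files(dir, pattern = "rps19|ndhf|ycf1", full.names = TRUE)
  als <- read_gene_alignments(keep)
  sm <- concatenate_alignments(als)
  expect_setequal(sm$taxa, c("taxA", "taxB"))
  pre <- tempfile()
  out <- write_supermatrix(sm, pre)
  back <- Biostrings::readDNAStringSet(out[1])
  expect_equal(as.character(back[["taxA"]]), unname(sm$matrix[["taxA"]]))
  phy <- readLines(out[2])
  expect_equal(phy[1], sprintf("%d %d", length(sm$taxa), sm$total_length))
  part <- readLines(out[3])
  expect_match(part[1], "^DNA, ")
})
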