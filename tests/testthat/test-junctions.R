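test_that("planted junction extensions are reported exactly", {
  res <- make_plastome(small_spec(71))
  p <- detect_partition(res$record, min_ir = 100)
  jr <- junction_report(res$record, p)
  sp <- jr[jr$placement == "spans" & !jr$pseudo, ]
  expect_setequal(sp$gene, c("rps19", "ndhF", "ycf1"))
  expect_equal(sp$bp_right[sp$gene == "rps19"], 110L)  # the IRb-extension figure
  expect_equal(sp$bp_left[sp$gene == "rps19"], 169L)
  expect_equal(sp$bp_left[sp$gene == "ndhF"], 40L)
  # spanning genes: the two sides add to the genomic span length
  expect_equal(sp$bp_left + sp$bp_right,
               c(rps19 = 279L, ndhF = 240L, ycf1 = 249L)[sp$gene],
               ignore_attr = TRUE)
  expect_true(all(sp$distance == 0L))
})

test_that("genes far from every junction are absent; nearby ones report distance", {
  seq <- random_dna(600)
  I <- random_dna(60)
  genome <- paste0(seq, I, random_dna(200), plastomics::revcomp(I))
  # mid-LSC gene far from all junctions under a 50 bp window
  feats <- list(gene_feature("mid", "PCG", list(interval(280, 310))),
                gene_feature("near", "PCG", list(interval(570, 590))))
  rec <- toy_record(genome, feats)
  p <- detect_partition(rec, min_ir = 30)
  jr <- junction_report(rec, p, window = 50)
  expect_false("mid" %in% jr$gene)
  near <- jr[jr$gene == "near", ]
  expect_equal(near$junction, "JLB")
  expect_equal(near$placement, "within-window-left")
  expect_equal(near$distance, 600L - 590L)
})

test_that("junction reports are rotation invariant", {
  res <- make_plastome(small_spec(83))
  p0 <- detect_partition(res$record, min_ir = 100)
  jr0 <- junction_report(res$record, p0)
  ord <- order(jr0$junction, jr0$gene, jr0$pseudo)
  for (off in c(250L, 2600L)) {
    rot <- rotate_record(res$record, off)
    jr1 <- junction_report(rot, detect_partition(rot, min_ir = 100))
    ord1 <- order(jr1$junction, jr1$gene, jr1$pseudo)
    expect_equal(jr1[ord1, c("junction", "gene", "pseudo", "placement",
                             "bp_left", "bp_right", "distance")],
                 jr0[ord, c("junction", "gene", "pseudo", "placement",
                            "bp_left", "bp_right", "distance")],
                 ignore_attr = TRUE)
  }
})

test_that("gene overlaps use half-open intersection on the circle", {
  seqs <- strrep("ACGT", 100)
  rec <- toy_record(seqs, list(
    gene_feature("a", "PCG", list(interval(10, 60))),
    gene_feature("b", "PCG", list(interval(20, 100))),
    gene_feature("c", "PCG", list(interval(60, 80))),
    gene_feature("d", "PCG", list(interval(380, 30, wraps = TRUE)))))
  expect_equal(gene_overlap(rec, "a", "b"), 40L)
  expect_equal(gene_overlap(rec, "a", "c"), 0L)   # adjacent, half-open
  expect_equal(gene_overlap(rec, "b", "d"), 10L)  # wrap-around intersection
  expect_error(gene_overlap(rec, "a", "zz"), "zz")
})

test_that("planted extensions and pseudo-copy overlaps are recovered across genomes", {
  overlaps <- integer(0)
  for (seed in 1:12) {
    set.seed(seed + 1000)
    e <- sample(34:59, 1)     # ndhF reach into the IRb
    res <- make_plastome(small_spec(seed + 200, ndhf_in_irb = e))
    p <- detect_partition(res$record, min_ir = 100)
    jr <- junction_report(res$record, p)
    sp <- jr[jr$placement == "spans" & !jr$pseudo, ]
    expect_equal(sp$bp_right[sp$gene == "rps19"], 110L)
    expect_equal(sp$bp_left[sp$gene == "ndhF"], e)
    ov <- gene_overlap(res$record, "ycf1", "ndhF",
                       pseudo_a = TRUE, pseudo_b = FALSE)
    expect_equal(ov, e)       # truncated ycf1 copy overlaps ndhF by its reach
    overlaps <- c(overlaps, ov)
  }
  expect_true(all(overlaps >= 34L & overlaps <= 59L))
})

test_that("cross-taxon comparison partitions taxa by junction diagnostics", {
  with_ext <- make_plastome(small_spec(301))
  no_ext_spec <- small_spec(302)
  no_ext_spec$junction_genes <- data.frame(
    name = c("rps19", "ndhF", "ycf1"), junction = c("JLB", "JSB", "JSA"),
    bp_upstream = c(279L, 40L, 99L), bp_downstream = c(1L, 200L, 150L),
    strand = c("-", "-", "+"), pseudo = FALSE, stringsAsFactors = FALSE)
  # rps19 wholly in the LSC except 1 bp: still "spans" but fails a >= 100 bp
  # extension requirement
  without_ext <- make_plastome(no_ext_spec)
  reports <- lapply(list(crass = with_ext, other = without_ext), function(r)
    junction_report(r$record, detect_partition(r$record, min_ir = 100)))
  cmp <- compare_junctions(reports, diagnostics = list(
    rps19_in_irb = list(gene = "rps19", junction = "JLB", min_extension = 100L)))
  expect_true(cmp$diagnostics["crass", "rps19_in_irb"])
  expect_false(cmp$diagnostics["other", "rps19_in_irb"])
  expect_error(compare_junctions(reports["crass"]), "two taxa")

  # identical taxa -> a single diagnostic class
  cmp2 <- compare_junctions(list(a = reports$crass, b = reports$crass),
                            diagnostics = list(
    rps19_in_irb = list(gene = "rps19", junction = "JLB", min_extension = 100L)))
  expect_true(all(cmp2$diagnostics[, 1]))
})
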