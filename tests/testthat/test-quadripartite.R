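test_that("a constructed toy genome is partitioned at the exact coordinates", {
  set.seed(101)
  Lseq <- random_dna(200); Cseq <- random_dna(80)
  repeat {                       # an IR segment that is not self-palindromic
    I <- random_dna(50)
    if (I != plastomics::revcomp(I)) break
  }
  seq <- paste0(Lseq, I, Cseq, plastomics::revcomp(I))
  rec <- toy_record(seq)
  p <- detect_partition(rec, min_ir = 20)
  expect_equal(p$lsc_len, 200L)
  expect_equal(p$ir_len, 50L)
  expect_equal(p$ssc_len, 80L)
  expect_equal(unname(p$junctions), c(200L, 250L, 330L, 0L))
  expect_identical(interval_seq(rec$seq, p$irb), I)
  expect_identical(interval_seq(rec$seq, p$ira), plastomics::revcomp(I))
})

test_that("a random sequence without repeats has no quadripartite structure", {
  set.seed(7)
  rec <- toy_record(random_dna(500))
  expect_error(detect_partition(rec, min_ir = 100), "no quadripartite")
})

test_that("tied repeat pairs inducing different partitions are an error", {
  set.seed(11)
  I <- "ACCGTAGGCTAATCCGGATTCGAATCGCCA"     # 30 bp, not self-complementary
  J <- "TTGACCATGCAGGACTATCAGCGCCATTGA"
  # flank every copy with A: A never complements A, so neither pair can
  # extend by chance and both stay exactly 30 bp
  seq <- paste0(random_dna(150), "A", I, "A", random_dna(60), "A",
                plastomics::revcomp(I), "A",
                random_dna(150), "A", J, "A", random_dna(60), "A",
                plastomics::revcomp(J), "A", random_dna(40))
  expect_error(detect_partition(toy_record(seq), min_ir = 25), "tie|ambiguous")
})

test_that("assign_region respects half-open junction conventions", {
  res <- make_plastome(small_spec(21))
  p <- detect_partition(res$record, min_ir = 100)
  j <- p$junctions
  expect_equal(assign_region(p, j[["JLB"]]), "IRb")
  expect_equal(assign_region(p, j[["JLB"]] - 1L), "LSC")
  expect_equal(assign_region(p, j[["JSB"]]), "SSC")
  expect_equal(assign_region(p, j[["JSA"]]), "IRa")
  expect_equal(assign_region(p, j[["JLA"]]), "LSC")
  expect_error(assign_region(p, genome_length(res$record)), "out of range")
  # construction map on a planted genome
  tr <- res$truth$partition
  pos <- c(0L, tr$lsc_len - 1L, tr$lsc_len, tr$lsc_len + tr$ir_len,
           tr$length - 1L)
  expect_equal(assign_region(p, pos), c("LSC", "LSC", "IRb", "SSC", "IRa"))
})

test_that("detection agrees with the quadratic oracle on random circular sequences", {
  set.seed(42)
  n_agree_structure <- 0L
  for (k in 1:30) {
    n <- sample(150:500, 1)
    seq <- random_dna(n)
    if (k %% 2 == 0) {            # plant an IR in half the cases
      I <- random_dna(sample(15:40, 1))
      seq <- paste0(substr(seq, 1, n %/% 2), I,
                    substr(seq, n %/% 2 + 1, n), plastomics::revcomp(I))
    }
    rec <- toy_record(seq)
    orc <- oracle_detect(seq, min_ir = 12)
    got <- tryCatch(detect_partition(rec, min_ir = 12),
                    error = function(e) conditionMessage(e))
    if (orc$status == "none") {
      expect_match(got, "no quadripartite")
    } else if (orc$status == "tie") {
      expect_match(got, "ambiguous")
    } else {
      expect_s3_class(got, "quadripartite_partition")
      expect_equal(got$lsc_len, orc$lsc)
      expect_equal(got$ssc_len, orc$ssc)
      expect_equal(got$ir_len, orc$ir)
      expect_equal(got$junctions, orc$junctions)
      n_agree_structure <- n_agree_structure + 1L
    }
  }
  expect_gt(n_agree_structure, 5L)   # the planted cases must exercise the path
})

test_that("planted partitions are recovered exactly across seeded genomes", {
  for (seed in 1:10) {
    set.seed(seed)
    lsc <- sample(1200:2200, 1); ssc <- sample(300:700, 1); ir <- sample(200:400, 1)
    sp <- plastome_spec(lsc_len = lsc, ssc_len = ssc, ir_len = ir,
                        junction_genes = data.frame(
                          name = "rps19", junction = "JLB", bp_upstream = 169L,
                          bp_downstream = 110L, strand = "-", pseudo = FALSE,
                          stringsAsFactors = FALSE),
                        planted_ssrs = default_planted_ssrs()[0, ],
                        n_cds = 2L, cds_len_range = c(60L, 100L),
                        n_cds_ir = 0L, seed = seed)
    res <- make_plastome(sp)
    p <- detect_partition(res$record, min_ir = 100)
    expect_equal(p$lsc_len, lsc)
    expect_equal(p$ssc_len, ssc)
    expect_equal(p$ir_len, ir)
    expect_equal(unname(p$junctions),
                 c(lsc, lsc + ir, lsc + ir + ssc, 0L))
  }
})

test_that("detection is rotation invariant in region lengths and sequences", {
  res <- make_plastome(small_spec(31))
  p0 <- detect_partition(res$record, min_ir = 100)
  s0 <- region_seqs(res$record, p0)
  for (off in c(137L, 1500L, genome_length(res$record) - 3L)) {
    rot <- rotate_record(res$record, off)
    p1 <- detect_partition(rot, min_ir = 100)
    expect_equal(p1$lsc_len, p0$lsc_len)
    expect_equal(p1$ssc_len, p0$ssc_len)
    expect_equal(p1$ir_len, p0$ir_len)
    expect_identical(region_seqs(rot, p1), s0)
  }
  # canonicalization puts the LSC at the origin
  rot <- rotate_record(res$record, 999L)
  can <- canonicalize_partition(rot, detect_partition(rot, min_ir = 100))
  expect_equal(can$partition$rotation, 0L)
  expect_equal(can$partition$junctions[["JLA"]], 0L)
  expect_identical(can$record$seq, res$record$seq)
})

test_that("partition invariants hold and the table mirrors BED conventions", {
  res <- make_plastome(small_spec(57))
  p <- detect_partition(res$record, min_ir = 100)
  L <- genome_length(res$record)
  expect_identical(interval_seq(res$record$seq, p$irb),
                   plastomics::revcomp(interval_seq(res$record$seq, p$ira)))
  expect_gte(p$lsc_len, p$ssc_len)
  expect_equal(p$lsc_len + p$ssc_len + 2L * p$ir_len, L)
  tab <- partition_table(p)
  expect_equal(tab$region, c("LSC", "IRb", "SSC", "IRa"))
  expect_equal(sum(tab$length), L)
})
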