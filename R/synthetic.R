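# Synthetic annotated plastomes with exact ground truth.
#
# The generator emits a circular quadripartite genome -- LSC + IRb + SSC +
# IRa with IRb the exact reverse complement of IRa -- carrying planted
# junction-spanning genes, planted SSR loci and coding sequences sampled
# i.i.d. from a codon profile.  Background sequence is sampled base-wise at
# the region GC target and then repaired by rejection so that no SSR above
# threshold and no inverted repeat half the planted IR length exists beyond
# the planted ones: recall = precision = 1 tests need clean ground truth.
# Everything is deterministic in the seed.

.comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Default codon sampling profile
#'
#' Sense-codon probabilities with a plastome-like shape: leucine the most
#' frequent amino acid, cysteine the rarest, and a clear preference for
#' A/T-ending codons within every synonymous family (weight 1.6 vs 0.4),
#' which keeps expected RSCU values well away from the preference
#' boundary at 1.
#'
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
default_codon_profile <- function() {
  aa_w <- c(L = 10.5, I = 8.3, S = 7.9, G = 7.1, R = 6.0, K = 6.0, E = 6.5,
            F = 5.1, T = 5.2, A = 5.3, V = 5.5, D = 4.2, N = 4.5, P = 4.1,
            Q = 3.3, T2 = 0, Y = 3.5, H = 2.3, M = 2.2, W = 1.8, C = 1.1)
  aa_w <- aa_w[names(aa_w) != "T2"]
  code <- .plastid_code()
  sense <- names(code)[code != "*"]
  third <- substr(sense, 3, 3)
  w_codon <- ifelse(third %in% c("A", "T"), 1.6, 0.4)
  prof <- numeric(length(sense)); names(prof) <- sense
  for (aa in unique(code[sense])) {
    fam <- sense[code[sense] == aa]
    wf <- w_codon[match(fam, sense)]
    prof[fam] <- aa_w[[aa]] * wf / sum(wf)
  }
  prof / sum(prof)
}

#' Default junction gene layout
#'
#' Emulates the conserved Crassulaceae-style junction architecture:
#' rps19 at JLB with 110 bp inside IRb, ndhF at JSB reaching 40 bp into
#' the IRb, and ycf1 spanning JSA; the generator's IR mirroring creates
#' the truncated ycf1 copy in the IRb that overlaps ndhF by those 40 bp.
#' Gene lengths are the canonical 279 / 2241 / 5598 bp.
#'
#' @return data.frame (name, junction, bp_upstream, bp_downstream, strand,
#'   pseudo).
#' @export
default_junction_genes <- function() {
  data.frame(
    name = c("rps19", "ndhF", "ycf1"),
    junction = c("JLB", "JSB", "JSA"),
    bp_upstream = c(169L, 40L, 1000L),
    bp_downstream = c(110L, 2201L, 4598L),
    strand = c("-", "-", "+"),
    pseudo = FALSE,
    stringsAsFactors = FALSE)
}

#' Default planted SSR set
#' @return data.frame (motif, repeats, region, offset).
#' @export
default_planted_ssrs <- function() {
  data.frame(
    motif = c("A", "T", "AT", "TTC", "A", "AAAT", "A", "AT"),
    repeats = c(10L, 12L, 6L, 4L, 9L, 3L, 8L, 5L),
    region = c("LSC", "LSC", "LSC", "LSC", "SSC", "SSC", "IRb", "SSC"),
    offset = c(500L, 5005L, 9200L, 14007L, 3301L, 4500L, 3000L, 6000L),
    stringsAsFactors = FALSE)
}

#' Build a synthetic plastome specification
#'
#' Defaults describe a realistic flowering-plant plastome: region sizes and
#' GC targets in the ranges reported for Sedum-like genomes, 60 coding
#' genes in the LSC plus one IR-duplicated gene, the conserved junction
#' gene layout of [default_junction_genes()] and the SSR set of
#' [default_planted_ssrs()].
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp (`lsc_len >= ssc_len`).
#' @param gc named numeric: GC fraction targets for `lsc`, `ssc`, `ir`.
#' @param junction_genes data.frame as [default_junction_genes()].
#' @param planted_ssrs data.frame as [default_planted_ssrs()].
#' @param cds_profile sense-codon sampling probabilities.
#' @param n_cds number of coding genes auto-placed in the LSC.
#' @param cds_len_range codon-count range (inclusive) for auto CDS lengths.
#' @param n_cds_ir coding genes placed inside the IRb (their IRa mirror is
#'   annotated as a functional duplicate).
#' @param annotate_mirrors annotate IR-mirrored fragments of junction genes
#'   as pseudogenes (the ycf1-pseudocopy pattern).
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @return list of class `"plastome_spec"`.
#' @export
plastome_spec <- function(lsc_len = 81700L, ssc_len = 16700L, ir_len = 25600L,
                          gc = c(lsc = 0.357, ssc = 0.319, ir = 0.43),
                          junction_genes = default_junction_genes(),
                          planted_ssrs = default_planted_ssrs(),
                          cds_profile = default_codon_profile(),
                          n_cds = 60L, cds_len_range = c(150L, 400L),
                          n_cds_ir = 1L, annotate_mirrors = TRUE,
                          seed = 1L) {
  if (lsc_len < ssc_len) stop("lsc_len must be >= ssc_len")
  stopifnot(all(c("lsc", "ssc", "ir") %in% names(gc)), all(gc > 0 & gc < 1))
  spec <- structure(list(
    lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
    ir_len = as.integer(ir_len), gc = gc,
    junction_genes = junction_genes, planted_ssrs = planted_ssrs,
    cds_profile = cds_profile, n_cds = as.integer(n_cds),
    cds_len_range = as.integer(cds_len_range),
    n_cds_ir = as.integer(n_cds_ir),
    annotate_mirrors = isTRUE(annotate_mirrors),
    seed = as.integer(seed)), class = "plastome_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  L <- with(spec, lsc_len + ssc_len + 2L * ir_len)
  jg <- spec$junction_genes
  if (nrow(jg)) {
    if (!all(jg$junction %in% c("JLB", "JSB", "JSA", "JLA")))
      stop("unknown junction in junction_genes")
    lim <- with(spec, c(JLB = lsc_len, JSB = ir_len, JSA = ssc_len, JLA = ir_len))
    lim2 <- with(spec, c(JLB = ir_len, JSB = ssc_len, JSA = ir_len, JLA = lsc_len))
    bad <- jg$bp_upstream >= lim[jg$junction] | jg$bp_downstream >= lim2[jg$junction] |
      jg$bp_upstream < 1L | jg$bp_downstream < 1L
    if (any(bad)) stop("junction gene does not fit its flanking regions: ",
                       paste(jg$name[bad], collapse = ", "))
  }
  ps <- spec$planted_ssrs
  if (nrow(ps)) {
    if (!all(ps$region %in% c("LSC", "IRb", "SSC", "IRa"))) stop("bad SSR region")
    rl <- with(spec, c(LSC = lsc_len, IRb = ir_len, SSC = ssc_len, IRa = ir_len))
    runlen <- nchar(ps$motif) * ps$repeats
    if (any(ps$offset < 1L | ps$offset + runlen + 1L > rl[ps$region]))
      stop("planted SSR outside its region (flank bases included)")
    if (!all(vapply(ps$motif, motif_is_primitive, logical(1))))
      stop("planted SSR motif must be primitive")
    thr <- ssr_default_thresholds()
    if (any(ps$repeats < thr[as.character(nchar(ps$motif))]))
      stop("planted SSR below reporting threshold")
  }
  invisible(spec)
}

# region start offsets in genome coordinates
region_starts <- function(spec) {
  c(LSC = 0L, IRb = spec$lsc_len, SSC = spec$lsc_len + spec$ir_len,
    IRa = spec$lsc_len + spec$ir_len + spec$ssc_len)
}

#' Generate a synthetic plastome with ground truth
#'
#' @param spec a [plastome_spec()].
#' @return list with `record` (a [plastome_record()]) and `truth` (the
#'   ground-truth sidecar: partition coordinates, planted feature map,
#'   planted SSR map in genome and IR-deduplicated coordinates, realized
#'   codon counts, and the seed).
#' @export
make_plastome <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  L <- with(spec, lsc_len + ssc_len + 2L * ir_len)
  rs <- region_starts(spec)
  jl <- c(JLB = rs[["IRb"]], JSB = rs[["SSC"]], JSA = rs[["IRa"]], JLA = 0L)
  g <- character(L)          # genome as chars, 1-based vector
  written <- logical(L)

  region_of_pos <- function(p) {   # p 0-based
    ifelse(p < rs[["IRb"]], "LSC",
           ifelse(p < rs[["SSC"]], "IRb",
                  ifelse(p < rs[["IRa"]], "SSC", "IRa")))
  }
  gc_of_pos <- function(p) {
    reg <- region_of_pos(p)
    unname(spec$gc[c(LSC = "lsc", IRb = "ir", SSC = "ssc", IRa = "ir")[reg]])
  }
  sample_bg <- function(p) {       # background base for 0-based positions p
    gcp <- gc_of_pos(p)
    vapply(gcp, function(x)
      sample(c("A", "T", "G", "C"), 1L,
             prob = c((1 - x) / 2, (1 - x) / 2, x / 2, x / 2)), character(1))
  }
  # write base chars at 0-based positions, respecting the IR mirror:
  # writing into IRa lands complemented at the mirrored IRb position
  mirror_pos <- function(p) rs[["IRb"]] + (L - 1L - p)   # IRa pos -> IRb pos
  put <- function(p, chars, force = FALSE) {
    in_ira <- p >= rs[["IRa"]]
    tp <- ifelse(in_ira, mirror_pos(p), p)
    tc <- ifelse(in_ira, .comp_map[chars], chars)
    sel <- force | !written[tp + 1L]
    g[tp[sel] + 1L] <<- tc[sel]
    written[tp[sel] + 1L] <<- TRUE
    invisible(NULL)
  }

  feats <- list(); truth_feats <- list()
  add_feat <- function(name, category, start, len, strand, pseudo) {
    s0 <- start %% L; e0 <- s0 + len
    iv <- interval(s0, if (e0 > L) e0 - L else e0, strand, wraps = e0 > L)
    feats[[length(feats) + 1L]] <<- gene_feature(name, category, list(iv), pseudo)
    truth_feats[[length(truth_feats) + 1L]] <<- data.frame(
      name = name, category = category, pseudo = pseudo, start = s0,
      length = len, strand = strand, wraps = e0 > L, stringsAsFactors = FALSE)
    invisible(NULL)
  }

  gen_cds <- function(len_bp) {
    stopifnot(len_bp %% 3L == 0L, len_bp >= 9L)
    n_body <- len_bp %/% 3L - 2L
    body <- sample(names(spec$cds_profile), n_body, replace = TRUE,
                   prob = spec$cds_profile)
    paste0("ATG", paste0(body, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L, prob = c(.5, .3, .2)))
  }
  gen_gene_content <- function(len_bp) {
    if (len_bp %% 3L == 0L && len_bp >= 9L) gen_cds(len_bp)
    else paste0(sample(c("A", "T", "G", "C"), len_bp, replace = TRUE,
                       prob = c(.31, .31, .19, .19)), collapse = "")
  }

  # ---- reserve + write planted junction genes -------------------------------
  jg <- spec$junction_genes
  jg_arcs <- list()
  if (nrow(jg)) for (i in seq_len(nrow(jg))) {
    jpos <- jl[[jg$junction[i]]]
    glen <- jg$bp_upstream[i] + jg$bp_downstream[i]
    s0 <- (jpos - jg$bp_upstream[i]) %% L
    content <- gen_gene_content(glen)
    if (jg$strand[i] == "-") content <- revcomp(content)
    put((s0 + seq_len(glen) - 1L) %% L, strsplit(content, "")[[1]])
    add_feat(jg$name[i], "PCG", s0, glen, jg$strand[i], jg$pseudo[i])
    jg_arcs[[i]] <- c(s0, glen)
    # annotate the IR-mirrored fragment of any arm inside an IR (e.g. the
    # truncated ycf1 copy and the rps19 fragment)
    if (spec$annotate_mirrors) {
      arc <- (s0 + seq_len(glen) - 1L) %% L
      for (ir in c("IRb", "IRa")) {
        lo <- rs[[ir]]
        inside <- arc[arc >= lo & arc < lo + spec$ir_len]
        if (length(inside) == 0L || length(inside) == glen) next
        other <- if (ir == "IRb") rs[["IRa"]] else rs[["IRb"]]
        marc <- other + (spec$ir_len - 1L - (inside - lo))
        add_feat(jg$name[i], "PCG", min(marc), length(inside),
                 if (jg$strand[i] == "+") "-" else "+", TRUE)
      }
    }
  }

  # ---- reserve + write planted SSRs ----------------------------------------
  ps <- spec$planted_ssrs
  truth_ssrs <- list()
  if (nrow(ps)) for (i in seq_len(nrow(ps))) {
    u <- nchar(ps$motif[i]); r <- ps$repeats[i]
    s0 <- rs[[ps$region[i]]] + ps$offset[i]
    runp <- s0 + seq_len(u * r) - 1L
    if (any(written[ifelse(runp >= rs[["IRa"]], mirror_pos(runp), runp) + 1L]))
      stop("planted SSR ", i, " overlaps previously planted content")
    put(runp, strsplit(strrep(ps$motif[i], r), "")[[1]])
    # blocking flanks: left base must differ from the base one unit right of
    # it; right flank likewise, so the run cannot extend in either direction
    lc <- substr(ps$motif[i], u, u)     # leftward extension needs s[-1] == motif's last char
    put((s0 - 1L) %% L, sample(setdiff(c("A", "C", "G", "T"), lc), 1L))
    rc <- substr(ps$motif[i], 1L, 1L)   # rightward extension needs s[end] == motif's first char
    put(s0 + u * r, sample(setdiff(c("A", "C", "G", "T"), rc), 1L))
    truth_ssrs[[i]] <- data.frame(
      motif = ps$motif[i], motif_class = motif_class(ps$motif[i]),
      unit_len = u, repeats = r, start = s0, region = ps$region[i],
      stringsAsFactors = FALSE)
  }
  # positions that repairs must never touch: planted runs plus their
  # blocking flanks, on both IR copies
  ssr_guard <- integer(0)
  if (nrow(ps)) for (i in seq_len(nrow(ps))) {
    u <- nchar(ps$motif[i]); r <- ps$repeats[i]
    s0 <- rs[[ps$region[i]]] + ps$offset[i]
    ssr_guard <- c(ssr_guard, (s0 - 1L):(s0 + u * r))
  }
  truth_ssrs <- if (length(truth_ssrs)) do.call(rbind, truth_ssrs)
                else data.frame(motif = character(), motif_class = character(),
                                unit_len = integer(), repeats = integer(),
                                start = integer(), region = character(),
                                stringsAsFactors = FALSE)

  # ---- auto-place CDSs in free LSC (and IRb) space -------------------------
  place_cds_batch <- function(n, lo, hi, prefix) {
    # walk from lo, skipping written stretches, margin 60 bp between genes
    pos <- lo
    placed <- 0L
    while (placed < n) {
      len_cod <- sample(seq(spec$cds_len_range[1], spec$cds_len_range[2]), 1L)
      len_bp <- 3L * len_cod
      repeat {
        if (pos + len_bp + 60L > hi)
          stop("infeasible spec: cannot place ", n, " CDSs in [", lo, ",", hi, ")")
        span <- pos + seq_len(len_bp + 14L) - 8L   # 7 bp clearance each side
        tp <- ifelse(span >= rs[["IRa"]], mirror_pos(span), span)
        hitw <- written[tp + 1L]
        if (!any(hitw)) break
        pos <- span[max(which(hitw))] + 8L
      }
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1L)
      cds <- gen_cds(len_bp)
      content <- if (strand == "-") revcomp(cds) else cds
      put(pos + seq_len(len_bp) - 1L, strsplit(content, "")[[1]])
      add_feat(sprintf("%s%03d", prefix, placed), "PCG", pos, len_bp, strand, FALSE)
      pos <- pos + len_bp + sample(60:160, 1L)
    }
  }
  if (spec$n_cds > 0L)
    place_cds_batch(spec$n_cds, 300L, spec$lsc_len - 300L, "orf")
  if (spec$n_cds_ir > 0L) {
    place_cds_batch(spec$n_cds_ir, rs[["IRb"]] + 50L,
                    rs[["SSC"]] - 50L, "irx")
    # annotate the IRa mirror of each IR gene as a functional duplicate
    for (k in which(vapply(feats, function(f) grepl("^irx", f$name), logical(1)))) {
      f <- feats[[k]]
      iv <- f$parts[[1]]
      glen <- iv$end - iv$start
      mstart <- rs[["IRa"]] + (spec$ir_len - (iv$end - rs[["IRb"]]))
      add_feat(f$name, "PCG", mstart, glen,
               if (iv$strand == "+") "-" else "+", FALSE)
    }
  }

  # ---- background fill ------------------------------------------------------
  unfilled <- which(!written[seq_len(rs[["IRa"]])]) - 1L  # only LSC+IRb+SSC
  g[unfilled + 1L] <- sample_bg(unfilled)
  refresh_ira <- function() {
    irb <- g[rs[["IRb"]] + seq_len(spec$ir_len)]
    g[rs[["IRa"]] + seq_len(spec$ir_len)] <<- rev(unname(.comp_map[irb]))
  }
  refresh_ira()

  # the IR partner of a position (identity outside the repeats)
  partner <- function(p) {
    ifelse(p >= rs[["IRb"]] & p < rs[["SSC"]],
           rs[["IRa"]] + (spec$ir_len - 1L - (p - rs[["IRb"]])),
           ifelse(p >= rs[["IRa"]], mirror_pos(p), p))
  }

  # resample the sense codon covering genome position p of a non-pseudo
  # feature, in the feature's own reading frame and strand
  resample_codon_at <- function(p) {
    for (f in feats) {
      if (f$pseudo) next
      iv <- f$parts[[1]]
      pos <- interval_positions(iv, L)
      if (!p %in% pos) next
      glen <- length(pos)
      if (glen %% 3L != 0L) next
      off <- match(p, pos) - 1L           # 0-based offset along the top strand arc
      cs_off <- if (iv$strand == "+") off - off %% 3L
                else glen - 3L * ((glen - 1L - off) %/% 3L) - 3L
      cod_pos <- pos[cs_off + 1:3]
      newc <- sample(names(spec$cds_profile), 1L, prob = spec$cds_profile)
      chars <- strsplit(if (iv$strand == "-") revcomp(newc) else newc, "")[[1]]
      put(cod_pos, chars, force = TRUE)
      refresh_ira()
      return(TRUE)
    }
    FALSE
  }

  # block accidental outward extension of the planted IR pair: the base just
  # upstream of IRb must not complement the base just downstream of IRa (and
  # likewise on the SSC side)
  fix_flank_pair <- function(p1, p2) {
    for (tries in 1:50) {
      if (g[p1 + 1L] != .comp_map[[g[p2 + 1L]]]) return(invisible(NULL))
      if (!written[p1 + 1L]) g[p1 + 1L] <<- sample_bg(p1)
      else if (!written[p2 + 1L]) g[p2 + 1L] <<- sample_bg(p2)
      else if (!resample_codon_at(p1) && !resample_codon_at(p2))
        stop("cannot block IR flank extension at ", p1, "/", p2)
    }
    stop("cannot block IR flank extension at ", p1, "/", p2)
  }
  fix_flank_pair(0L, rs[["IRb"]] - 1L)           # extension across JLA/JLB
  fix_flank_pair(rs[["SSC"]], rs[["IRa"]] - 1L)  # extension across JSB/JSA
  refresh_ira()

  # ---- rejection repair: exactly the planted SSR set, no stray IRs ---------
  lin_len <- rs[["IRa"]]
  planted_lin <- ssr_truth_linearized(truth_ssrs, spec, rs)
  thr <- ssr_default_thresholds()
  for (iter in 1:100) {
    lin <- paste0(g[seq_len(lin_len)], collapse = "")
    found <- scan_ssrs(lin, thr)
    extra <- setdiff(paste(found$start, found$end),
                     paste(planted_lin$start, planted_lin$end))
    missing <- setdiff(paste(planted_lin$start, planted_lin$end),
                       paste(found$start, found$end))
    if (length(extra) == 0L) {
      if (length(missing)) stop("internal error: planted SSR lost during generation")
      break
    }
    for (key in extra) {
      se <- as.integer(strsplit(key, " ")[[1]])
      span <- seq(se[1], se[2] - 1L)          # 0-based positions in linearized
      free <- span[!written[span + 1L]]
      if (length(free)) {
        g[free + 1L] <- sample_bg(free)
      } else if (!any(vapply(span, resample_codon_at, logical(1))) &&
                 !any(vapply(partner(span), resample_codon_at, logical(1)))) {
        # planted-gene content without a codon frame: overwrite a single
        # base, never inside a planted SSR run or its blocking flanks
        safe <- setdiff(span, c(ssr_guard, partner(ssr_guard)))
        if (length(safe) == 0L) stop("cannot repair accidental SSR at ", key)
        pick <- safe[ceiling(length(safe) / 2)]
        put(pick, sample(setdiff(c("A", "C", "G", "T"), g[pick + 1L]), 1L),
            force = TRUE)
        refresh_ira()
      }
    }
    refresh_ira()
    if (iter == 100L) stop("SSR repair did not converge")
  }

  # stray inverted repeats: anything half the planted IR length or more
  seqstr <- paste0(g, collapse = "")
  t_ir <- max(24L, spec$ir_len %/% 2L)
  for (iter in 1:50) {
    cand <- revcomp_repeat_candidates(seqstr, t_ir)
    planted_a <- min(rs[["IRb"]], rs[["IRa"]]); planted_b <- max(rs[["IRb"]], rs[["IRa"]])
    stray <- cand[!(cand$a == planted_a & cand$b == planted_b &
                      cand$len == spec$ir_len), , drop = FALSE]
    if (nrow(stray) == 0L) break
    span <- (stray$a[1] + seq_len(stray$len[1]) - 1L) %% L
    tp <- ifelse(span >= rs[["IRa"]], vapply(span, mirror_pos, numeric(1)), span)
    free <- unique(tp[!written[tp + 1L]])
    if (length(free) == 0L) stop("cannot repair stray inverted repeat")
    g[free + 1L] <- sample_bg(free)
    refresh_ira()
    seqstr <- paste0(g, collapse = "")
    if (iter == 50L) stop("inverted-repeat repair did not converge")
  }

  record <- plastome_record(sprintf("synthetic_seed%d", spec$seed),
                            paste0(g, collapse = ""), TRUE, feats)
  cds <- tryCatch(suppressWarnings(cds_sequences(record)), error = function(e) character())
  realized <- if (length(cds))
    suppressWarnings(codon_table_from_seqs(cds, record$id)$counts)
  else setNames(integer(64), all_codons())
  truth <- list(
    partition = list(lsc_len = spec$lsc_len, ssc_len = spec$ssc_len,
                     ir_len = spec$ir_len, length = L,
                     junctions = as.list(jl)),
    features = if (length(truth_feats)) do.call(rbind, truth_feats) else NULL,
    ssrs = truth_ssrs,
    ssrs_linearized = planted_lin,
    codon_counts = as.list(realized),
    seed = spec$seed)
  list(record = record, truth = truth)
}

# planted SSR coordinates on the IR-deduplicated (LSC+IRb+SSC) sequence;
# a locus planted in IRa maps to the retained IRb copy with the motif
# reverse-complemented
ssr_truth_linearized <- function(truth_ssrs, spec, rs) {
  if (nrow(truth_ssrs) == 0L)
    return(data.frame(motif = character(), motif_class = character(),
                      unit_len = integer(), repeats = integer(),
                      start = integer(), end = integer(), region = character(),
                      stringsAsFactors = FALSE))
  L <- rs[["IRa"]] + spec$ir_len
  rows <- lapply(seq_len(nrow(truth_ssrs)), function(i) {
    r <- truth_ssrs[i, ]
    runlen <- r$unit_len * r$repeats
    if (r$region == "IRa") {
      mstart <- rs[["IRb"]] + (L - (r$start + runlen))
      data.frame(motif = revcomp(r$motif), motif_class = r$motif_class,
                 unit_len = r$unit_len, repeats = r$repeats, start = mstart,
                 end = mstart + runlen, region = "IRb", stringsAsFactors = FALSE)
    } else {
      data.frame(motif = r$motif, motif_class = r$motif_class,
                 unit_len = r$unit_len, repeats = r$repeats, start = r$start,
                 end = r$start + runlen, region = r$region,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Generate a comparative panel of synthetic taxa
#'
#' Applies per-taxon modifications to a base specification and generates
#' one plastome per taxon. Each taxon draws from its own seed
#' (`base$seed + index`, overridable via the edit list), so panels are
#' reproducible but taxa are independent.
#'
#' @param base a [plastome_spec()].
#' @param edits named list: taxon label -> list of spec fields to override
#'   (e.g. `cds_profile`, `junction_genes`, `planted_ssrs`, `seed`).
#'   An empty list keeps the base spec.
#' @return named list: taxon -> list(record, truth); record ids are the
#'   taxon labels.
#' @export
make_taxon_set <- function(base, edits) {
  stopifnot(length(names(edits)) == length(edits))
  out <- list()
  for (i in seq_along(edits)) {
    sp <- base
    for (fld in names(edits[[i]])) sp[[fld]] <- edits[[i]][[fld]]
    if (!"seed" %in% names(edits[[i]])) sp$seed <- base$seed + i
    validate_spec(sp)
    res <- make_plastome(sp)
    res$record$id <- names(edits)[i]
    res$truth$taxon <- names(edits)[i]
    out[[names(edits)[i]]] <- res
  }
  out
}

#' Write a synthetic plastome and its ground truth to disk
#'
#' Emits a GenBank flat file plus a JSON sidecar with the full ground
#' truth (partition, features, SSRs, codon counts, seed).
#'
#' @param result a [make_plastome()] result.
#' @param dir output directory.
#' @return invisible character vector (GenBank path, JSON path).
#' @export
write_synthetic <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(dir, paste0(result$record$id, ".gb"))
  js <- file.path(dir, paste0(result$record$id, ".truth.json"))
  write_genbank(result$record, gb)
  jsonlite::write_json(result$truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(gb, js))
}
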