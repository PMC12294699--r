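# Quadripartite structure detection.
#
# The LSC/IRb/SSC/IRa layout is recovered from sequence alone: the inverted
# repeat is the longest pair of disjoint, exact reverse-complement copies on
# the circular sequence.  Candidates are the maximal self-complementary
# matches (extension by one base in either direction breaks the match) whose
# two copies are disjoint on the circle; the partition is induced by the
# longest such pair.

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the longest pair of disjoint, exact reverse-complement repeats of
#' length at least `min_ir` and partitions the circle into LSC, IRb, SSC and
#' IRa. The longer single-copy segment is the LSC; IRb is the repeat copy
#' immediately downstream of the LSC. Coordinates are reported on the input
#' record; `rotation` gives the position of the first LSC base, so rotating
#' the record by `rotation` places the partition in canonical order starting
#' at position 0 (see [canonicalize_partition()]).
#'
#' @param record a circular [plastome_record()].
#' @param min_ir minimum repeat length in bp (default 1000; at least 100 is
#'   recommended to avoid small dispersed repeats).
#' @return A list of class `"quadripartite_partition"` with intervals `lsc`,
#'   `irb`, `ssc`, `ira`, a named integer vector `junctions`
#'   (`JLB`, `JSB`, `JSA`, `JLA`: the first base of IRb, SSC, IRa and LSC),
#'   region lengths, the genome `length` and the canonical `rotation`.
#' @export
detect_partition <- function(record, min_ir = 1000L) {
  if (!record$circular) stop("quadripartite detection requires a circular record")
  L <- genome_length(record)
  if (2L * min_ir >= L) stop("no quadripartite structure: genome shorter than two repeats")
  cand <- revcomp_repeat_candidates(record$seq, min_ir)
  if (nrow(cand) == 0L)
    stop("no quadripartite structure: no disjoint inverted repeat of length >= ",
         min_ir)
  best_len <- max(cand$len)
  best <- cand[cand$len == best_len, , drop = FALSE]
  if (nrow(best) > 1L) {
    desc <- apply(best, 1L, function(r)
      sprintf("[%d,%d)+[%d,%d)", r["a"], r["a"] + r["len"], r["b"], r["b"] + r["len"]))
    stop("ambiguous quadripartite structure: ", nrow(best),
         " repeat pairs tie at length ", best_len, ": ",
         paste(desc, collapse = " vs "))
  }
  build_partition(record, best$a[1], best$b[1], best$len[1])
}

# All maximal exact reverse-complement matches of length >= min_len whose two
# copies are disjoint on the circle, as a data.frame (a, b, len) in 0-based
# circle coordinates with a <= b.  Seed-and-extend with unit-step seeds on
# the doubled sequence; a run of consecutive matching seeds is exactly a
# maximal match, since any flanking base match would imply a matching
# flanking seed.
revcomp_repeat_candidates <- function(seq, min_len) {
  L <- nchar(seq)
  k <- min(31L, as.integer(min_len))
  x <- paste0(seq, seq)
  y <- revcomp(x)
  n2 <- 2L * L
  starts <- seq_len(n2 - k + 1L)
  xk <- substring(x, starts, starts + k - 1L)
  yk <- substring(y, starts, starts + k - 1L)
  # drop seeds containing N: N never matches anything
  okx <- !grepl("N", xk, fixed = TRUE)
  oky <- !grepl("N", yk, fixed = TRUE)
  dfx <- data.frame(i = starts[okx], key = xk[okx], stringsAsFactors = FALSE)
  dfy <- data.frame(j = starts[oky], key = yk[oky], stringsAsFactors = FALSE)
  hits <- merge(dfx, dfy, by = "key")
  if (nrow(hits) == 0L) return(empty_candidates())
  d <- hits$i - hits$j
  ord <- order(d, hits$i)
  i <- hits$i[ord]; dd <- d[ord]
  newrun <- c(TRUE, diff(i) != 1L | diff(dd) != 0L)
  run_id <- cumsum(newrun)
  run_start <- i[newrun]
  run_len <- as.integer(tabulate(run_id))
  match_len <- run_len + k - 1L
  j_start <- run_start - dd[newrun]
  keep <- match_len >= min_len & match_len <= L %/% 2L
  if (!any(keep)) return(empty_candidates())
  mi <- run_start[keep]; mj <- j_start[keep]; ml <- match_len[keep]
  # map the y-side interval back to top-strand circle coordinates
  a <- (mi - 1L) %% L
  b <- (n2 - mj - ml + 1L) %% L
  lo <- pmin(a, b); hi <- pmax(a, b)
  cand <- unique(data.frame(a = lo, b = hi, len = ml))
  disj <- vapply(seq_len(nrow(cand)), function(r) {
    circ_disjoint(cand$a[r], cand$b[r], cand$len[r], L)
  }, logical(1))
  cand <- cand[disj, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

empty_candidates <- function() data.frame(a = integer(), b = integer(), len = integer())

# are [a, a+len) and [b, b+len) disjoint (and distinct) on a circle of length L?
circ_disjoint <- function(a, b, len, L) {
  if (a == b) return(FALSE)
  g1 <- (b - (a + len)) %% L
  g2 <- (a - (b + len)) %% L
  g1 + g2 + 2L * len == L
}

build_partition <- function(record, a, b, len, check = TRUE) {
  L <- genome_length(record)
  g_after_a <- (b - (a + len)) %% L       # gap from end of copy A to start of copy B
  g_after_b <- (a - (b + len)) %% L
  # the longer gap is the LSC; IRb is the repeat copy that follows the LSC
  if (g_after_a >= g_after_b) {
    lsc_start <- (a + len) %% L; lsc_len <- g_after_a
    irb_start <- b; ssc_start <- (b + len) %% L; ssc_len <- g_after_b
    ira_start <- a
  } else {
    lsc_start <- (b + len) %% L; lsc_len <- g_after_b
    irb_start <- a; ssc_start <- (a + len) %% L; ssc_len <- g_after_a
    ira_start <- b
  }
  mk <- function(s, l) {
    e <- s + l
    interval(s, if (e > L) e - L else e, "+", wraps = e > L)
  }
  part <- structure(list(
    lsc = mk(lsc_start, lsc_len), irb = mk(irb_start, len),
    ssc = mk(ssc_start, ssc_len), ira = mk(ira_start, len),
    junctions = c(JLB = irb_start, JSB = ssc_start,
                  JSA = ira_start, JLA = lsc_start),
    lsc_len = lsc_len, ssc_len = ssc_len, ir_len = len,
    length = L, rotation = lsc_start
  ), class = "quadripartite_partition")
  if (check) {
    stopifnot(lsc_len + ssc_len + 2L * len == L)
    if (interval_seq(record$seq, part$irb) !=
        revcomp(interval_seq(record$seq, part$ira)))
      stop("internal error: IRb is not the exact reverse complement of IRa")
  }
  part
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite_partition> L=%d: LSC %d bp, IR %d bp (x2), SSC %d bp; rotation %d\n",
              x$length, x$lsc_len, x$ir_len, x$ssc_len, x$rotation))
  j <- x$junctions
  cat(sprintf("  junctions JLB=%d JSB=%d JSA=%d JLA=%d\n", j["JLB"], j["JSB"], j["JSA"], j["JLA"]))
  invisible(x)
}

#' Region label of a genomic position
#'
#' @param partition a [detect_partition()] result.
#' @param pos 0-based position (vectorized).
#' @return character vector over `{"LSC","IRb","SSC","IRa"}`.
#' @export
assign_region <- function(partition, pos) {
  L <- partition$length
  if (any(pos < 0L | pos >= L)) stop("position out of range [0, ", L, ")")
  inside <- function(iv, p) {
    if (iv$wraps) p >= iv$start | p < iv$end else p >= iv$start & p < iv$end
  }
  out <- rep(NA_character_, length(pos))
  for (reg in c("LSC", "IRb", "SSC", "IRa")) {
    iv <- partition[[tolower(reg)]]
    if (interval_length(iv, L) > 0L) out[inside(iv, pos)] <- reg
  }
  out
}

#' Extract the four region sequences
#' @param record the record the partition was detected on.
#' @param partition a [detect_partition()] result.
#' @return named character vector (`lsc`, `irb`, `ssc`, `ira`).
#' @export
region_seqs <- function(record, partition) {
  c(lsc = interval_seq(record$seq, partition$lsc),
    irb = interval_seq(record$seq, partition$irb),
    ssc = interval_seq(record$seq, partition$ssc),
    ira = interval_seq(record$seq, partition$ira))
}

#' Rotate a record and its partition into canonical orientation
#'
#' After canonicalization position 0 is the first LSC base and regions run
#' LSC, IRb, SSC, IRa in order.
#'
#' @param record a circular [plastome_record()].
#' @param partition the partition detected on `record`.
#' @return list with the rotated `record` and shifted `partition`.
#' @export
canonicalize_partition <- function(record, partition) {
  off <- partition$rotation
  rec2 <- rotate_record(record, off)
  L <- partition$length
  shift <- function(iv) {
    s <- (iv$start - off) %% L
    e_raw <- s + interval_length(iv, L)
    interval(s, if (e_raw > L) e_raw - L else e_raw, iv$strand, wraps = e_raw > L)
  }
  p2 <- partition
  p2$lsc <- shift(partition$lsc); p2$irb <- shift(partition$irb)
  p2$ssc <- shift(partition$ssc); p2$ira <- shift(partition$ira)
  p2$junctions <- (partition$junctions - off) %% L
  p2$rotation <- 0L
  list(record = rec2, partition = p2)
}

#' Partition report as a data frame
#'
#' One row per region with 0-based half-open coordinates (BED-compatible).
#'
#' @param partition a [detect_partition()] result.
#' @return data.frame with columns region, start, end, length, wraps.
#' @export
partition_table <- function(partition) {
  L <- partition$length
  rows <- lapply(c("LSC", "IRb", "SSC", "IRa"), function(reg) {
    iv <- partition[[tolower(reg)]]
    data.frame(region = reg, start = iv$start, end = iv$end,
               length = interval_length(iv, L), wraps = iv$wraps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
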