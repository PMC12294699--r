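# Base composition, GC content and strand-asymmetry (skew) statistics.
#
# AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C).  Both are
# homogeneous of degree zero, so they can be computed from counts or from
# percentages interchangeably.  N bases are excluded from all denominators.

#' Base composition and skew of a nucleotide sequence
#'
#' @param seq nucleotide string over `{A,C,G,T,N}` (case-insensitive), or a
#'   named numeric vector of base counts/percentages with names in
#'   `A,C,G,T` (useful for recomputing skews from published composition
#'   tables).
#' @return list of class `"composition_stats"`: integer counts (when a
#'   sequence was given), `pct_*` percentages over non-N bases, `gc_pct`,
#'   `at_pct`, `at_skew` and `gc_skew`. A skew whose denominator is zero is
#'   `NA`, never 0.
#' @export
composition <- function(seq) {
  if (is.character(seq)) {
    seq <- toupper(seq)
    ss <- Biostrings::DNAString(seq)
    af <- Biostrings::alphabetFrequency(ss)
    counts <- c(A = af[["A"]], C = af[["C"]], G = af[["G"]], T = af[["T"]])
    n_other <- nchar(seq) - sum(counts)
    if (sum(counts) == 0L) stop("sequence has no A/C/G/T bases")
  } else {
    counts <- seq[c("A", "C", "G", "T")]
    if (anyNA(counts)) stop("count vector must have names A, C, G, T")
    n_other <- 0L
  }
  tot <- sum(counts)
  pct <- 100 * counts / tot
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts, n = n_other, total = tot,
    pct_a = pct[["A"]], pct_c = pct[["C"]], pct_g = pct[["G"]], pct_t = pct[["T"]],
    at_pct = 100 * at / tot, gc_pct = 100 * gc / tot,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("composition: %s bp  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%  GC %.2f%%  AT-skew %.5f  GC-skew %.5f\n",
              format(x$total, big.mark = ","), x$pct_a, x$pct_c, x$pct_g, x$pct_t,
              x$gc_pct, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Per-region composition statistics
#'
#' Computes [composition()] for the LSC, the SSC, a single IR copy and the
#' whole genome, plus (when the record carries features) the concatenated
#' CDS, tRNA and rRNA sequences.
#'
#' @param record a [plastome_record()].
#' @param partition the [detect_partition()] result for `record`.
#' @return named list of `composition_stats` with elements `overall`, `lsc`,
#'   `ssc`, `ir`, and, if features exist, `cds`, `trna`, `rrna`.
#' @export
region_composition <- function(record, partition) {
  rs <- region_seqs(record, partition)
  out <- list(overall = composition(record$seq),
              lsc = composition(rs[["lsc"]]),
              ssc = composition(rs[["ssc"]]),
              ir = composition(rs[["irb"]]))
  if (length(record$features)) {
    cats <- vapply(record$features, `[[`, character(1), "category")
    pse <- vapply(record$features, `[[`, logical(1), "pseudo")
    for (sel in c(cds = "PCG", trna = "tRNA", rrna = "rRNA")) {
      feats <- record$features[cats == sel & !pse]
      nm <- names(which(c(cds = "PCG", trna = "tRNA", rrna = "rRNA") == sel))
      if (length(feats)) {
        cat_seq <- paste0(vapply(feats, function(f) feature_seq(record, f),
                                 character(1)), collapse = "")
        out[[nm]] <- composition(cat_seq)
      }
    }
  }
  out
}

#' Composition by codon position
#'
#' Splits a set of coding sequences into codon positions 1, 2, 3 and
#' computes composition per position; the headline statistic is the A+T
#' percentage per position. CDSs whose length is not divisible by 3 are
#' excluded with a warning reporting how many were dropped.
#'
#' @param cds_set character vector of CDS nucleotide sequences.
#' @return list with `pos1`, `pos2`, `pos3` (`composition_stats`),
#'   `at_pct` (numeric length 3) and `n_excluded`.
#' @export
codon_position_composition <- function(cds_set) {
  if (length(cds_set) == 0L) stop("empty CDS set")
  ok <- nchar(cds_set) %% 3L == 0L & nchar(cds_set) > 0L
  if (!all(ok))
    warning(sum(!ok), " CDS(s) with length not divisible by 3 excluded")
  cds_set <- cds_set[ok]
  if (length(cds_set) == 0L) stop("no CDS with length divisible by 3")
  all_seq <- paste0(toupper(cds_set), collapse = "")
  chars <- strsplit(all_seq, "")[[1]]
  posidx <- rep_len(1:3, length(chars))
  res <- lapply(1:3, function(p) composition(paste0(chars[posidx == p], collapse = "")))
  names(res) <- c("pos1", "pos2", "pos3")
  res$at_pct <- vapply(res[1:3], `[[`, numeric(1), "at_pct")
  res$n_excluded <- sum(!ok)
  res
}

#' Composition report table
#'
#' One row per sequence/region with the columns of a standard plastome
#' composition table (length, T%, C%, A%, G%, AT%, AT-skew, GC-skew),
#' rounded to report precision (percentages 2 dp, skews 5 dp).
#'
#' @param stats named list of `composition_stats`.
#' @return data.frame.
#' @export
composition_table <- function(stats) {
  rows <- lapply(names(stats), function(nm) {
    s <- stats[[nm]]
    data.frame(name = nm, length = s$total,
               pct_t = round(s$pct_t, 2), pct_c = round(s$pct_c, 2),
               pct_a = round(s$pct_a, 2), pct_g = round(s$pct_g, 2),
               at_pct = round(s$at_pct, 2),
               at_skew = round(s$at_skew, 5), gc_skew = round(s$gc_skew, 5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
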