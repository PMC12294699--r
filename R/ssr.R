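# Perfect microsatellite (SSR) detection under MISA-style criteria.
#
# A locus is a maximal perfect tandem run of a primitive 1-6 bp motif
# meeting the per-unit-length repeat threshold.  A run is reported once, at
# its smallest primitive unit: an (AT)6 run is one dinucleotide locus, never
# (ATAT)3 and never also shorter sub-loci.  Non-ACGT characters break runs.

#' Default SSR repeat-count thresholds
#'
#' 8 repeats for mononucleotides, 4 for di- and trinucleotides, 3 for
#' tetra-, penta- and hexanucleotides.
#' @return named integer vector indexed by unit length `1..6`.
#' @export
ssr_default_thresholds <- function() {
  c(`1` = 8L, `2` = 4L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

# smallest period of a motif; motif is primitive iff period == nchar(motif)
motif_is_primitive <- function(motif) {
  u <- nchar(motif)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), u %/% p)) return(FALSE)
  }
  TRUE
}

#' Standardized motif class
#'
#' The lexicographic minimum over all cyclic rotations of the motif and of
#' its reverse complement, so `A`/`T` collapse to class `"A"` and `AT`/`TA`
#' to `"AT"` — the convention of plastome SSR reports.
#'
#' @param motif repeat unit as observed.
#' @return canonical class string (vectorized).
#' @export
motif_class <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- function(s) vapply(seq_len(u) - 1L, function(r)
      paste0(substr(s, r + 1L, u), substr(s, 1L, r)), character(1))
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a sequence for perfect SSRs
#'
#' Finds all maximal perfect tandem runs whose primitive unit length is
#' 1-6 bp and whose complete-repeat count meets the threshold for that unit
#' length. Runs are trimmed to complete units (anchored at the run start).
#' In the rare case of two qualifying loci overlapping, the earlier-starting
#' (then longer, then smaller-unit) locus wins, so reported loci never
#' overlap.
#'
#' @param seq nucleotide string.
#' @param thresholds named vector unit length -> minimum repeats
#'   (default [ssr_default_thresholds()]).
#' @return data.frame with columns `motif`, `motif_class`, `unit_len`,
#'   `repeats`, `start`, `end` (0-based half-open), sorted by start.
#' @export
scan_ssrs <- function(seq, thresholds = ssr_default_thresholds()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(motif = character(), motif_class = character(),
                      unit_len = integer(), repeats = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  chars <- strsplit(seq, "")[[1]]
  valid <- chars %in% c("A", "C", "G", "T")
  cand <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    if (is.null(thr) || n < u * thr) next
    # eq[i] TRUE when position i matches position i+u (1-based)
    m <- n - u
    if (m < 1L) next
    eq <- chars[seq_len(m)] == chars[seq_len(m) + u] &
      valid[seq_len(m)] & valid[seq_len(m) + u]
    r <- rle(eq)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= u * (thr - 1L))) {
      a <- starts_at[ri]                # run covers positions a .. ends_at[ri]+u
      run_len <- r$lengths[ri] + u      # total bases with period u
      reps <- run_len %/% u
      if (reps < thr) next
      motif <- substr(seq, a, a + u - 1L)
      if (!motif_is_primitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, unit_len = u, repeats = reps,
        start = a - 1L, end = a - 1L + reps * u, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  df <- do.call(rbind, cand)
  df <- df[order(df$start, -(df$end - df$start), df$unit_len), , drop = FALSE]
  keep <- logical(nrow(df)); last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) { keep[i] <- TRUE; last_end <- df$end[i] }
  }
  df <- df[keep, , drop = FALSE]
  df$motif_class <- motif_class(df$motif)
  rownames(df) <- NULL
  df[, c("motif", "motif_class", "unit_len", "repeats", "start", "end")]
}

#' Scan a plastome for SSRs with one IR copy removed
#'
#' Scanning runs on the linearized LSC + IRb + SSC sequence (IRa, the copy
#' following the SSC in canonical order, is removed so repeats inside the
#' IR are reported once). Loci are assigned to the region containing their
#' start position.
#'
#' @param record a [plastome_record()].
#' @param partition the [detect_partition()] result for `record`.
#' @param thresholds see [scan_ssrs()].
#' @return list with `loci` (the [scan_ssrs()] data.frame plus a `region`
#'   column; coordinates are on the canonically rotated genome) and
#'   `summary` (counts by unit length, motif class and region).
#' @export
scan_plastome_ssrs <- function(record, partition,
                               thresholds = ssr_default_thresholds()) {
  rs <- region_seqs(record, partition)
  lin <- paste0(rs[["lsc"]], rs[["irb"]], rs[["ssc"]])
  loci <- scan_ssrs(lin, thresholds)
  jlb <- partition$lsc_len
  jsb <- jlb + partition$ir_len
  loci$region <- ifelse(loci$start < jlb, "LSC",
                        ifelse(loci$start < jsb, "IRb", "SSC"))
  list(loci = loci, summary = ssr_summary(loci))
}

#' Summarize SSR loci
#' @param loci a loci data.frame from [scan_ssrs()] / [scan_plastome_ssrs()].
#' @return list of tables: `by_unit_len`, `by_class`, `by_region` (when a
#'   region column exists), and `total`.
#' @export
ssr_summary <- function(loci) {
  out <- list(total = nrow(loci),
              by_unit_len = table(factor(loci$unit_len, levels = 1:6)),
              by_class = sort(table(loci$motif_class), decreasing = TRUE))
  if ("region" %in% names(loci))
    out$by_region <- table(factor(loci$region, levels = c("LSC", "IRb", "SSC", "IRa")))
  out
}
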