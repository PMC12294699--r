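#' @import Biostrings
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# ---- Interval model ---------------------------------------------------------
# Internal coordinates are 0-based half-open on the top strand.  An interval
# with wraps = TRUE is interpreted as [start, L) followed by [0, end) on a
# circular sequence of length L.

#' Create a genomic interval
#'
#' Intervals are 0-based half-open on the top strand. A wrapping interval
#' (`wraps = TRUE`) crosses the circular origin and covers `[start, L)`
#' followed by `[0, end)` on a sequence of length `L`.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @param wraps logical; does the interval cross the origin?
#' @return A list of class `"interval"`.
#' @export
interval <- function(start, end, strand = "+", wraps = FALSE) {
  stopifnot(start >= 0, end >= 0, strand %in% c("+", "-"))
  if (!wraps && end < start) stop("interval end < start without wraps")
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand, wraps = isTRUE(wraps)),
            class = "interval")
}

#' Interval length in bp
#' @param iv an [interval()].
#' @param L genome length, required when `iv$wraps`.
#' @return integer length.
#' @export
interval_length <- function(iv, L = NULL) {
  if (iv$wraps) {
    if (is.null(L)) stop("genome length required for a wrapping interval")
    (L - iv$start) + iv$end
  } else {
    iv$end - iv$start
  }
}

# 0-based positions covered by an interval, in 5'->3' top-strand order
interval_positions <- function(iv, L) {
  if (iv$wraps) c(seq.int(iv$start, L - 1L), seq.int(0L, length.out = iv$end))
  else seq.int(iv$start, length.out = iv$end - iv$start)
}

# Extract the top-strand sequence of an interval from a character scalar
interval_seq <- function(seq, iv) {
  L <- nchar(seq)
  if (iv$wraps) {
    paste0(substr(seq, iv$start + 1L, L), substr(seq, 1L, iv$end))
  } else {
    substr(seq, iv$start + 1L, iv$end)
  }
}

# Overlap length of two intervals on a circle of length L
interval_overlap <- function(a, b, L) {
  seg <- function(iv) {
    if (iv$wraps) rbind(c(iv$start, L), c(0L, iv$end))
    else rbind(c(iv$start, iv$end))
  }
  sa <- seg(a); sb <- seg(b)
  tot <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    lo <- max(sa[i, 1], sb[j, 1]); hi <- min(sa[i, 2], sb[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  as.integer(tot)
}

# ---- Gene features ----------------------------------------------------------

#' Create a gene feature
#'
#' A feature owns one or more intervals (`parts`), ordered in transcript
#' order; minus-strand parts are reverse-complemented at extraction time.
#'
#' @param name gene symbol (canonical mixed case preserved, e.g. `ycf1`).
#' @param category one of `"PCG"`, `"tRNA"`, `"rRNA"`.
#' @param parts list of [interval()] in transcript order.
#' @param pseudo logical; pseudogenes are never translated.
#' @param record_id id of the owning record.
#' @return A list of class `"gene_feature"`.
#' @export
gene_feature <- function(name, category, parts, pseudo = FALSE,
                         record_id = NA_character_) {
  stopifnot(category %in% c("PCG", "tRNA", "rRNA"), length(parts) >= 1)
  structure(list(name = trimws(name), category = category,
                 pseudo = isTRUE(pseudo), parts = parts,
                 record_id = record_id),
            class = "gene_feature")
}

# genomic span of a feature: the minimal interval covering all parts.
# On a circular genome a span crossing the origin is detected from the parts.
feature_span <- function(feat, L) {
  st <- vapply(feat$parts, `[[`, integer(1), "start")
  en <- vapply(feat$parts, `[[`, integer(1), "end")
  wr <- vapply(feat$parts, `[[`, logical(1), "wraps")
  if (any(wr)) {
    # normalize by unwrapping past L, then reduce mod L
    lo <- min(st); hi <- max(ifelse(wr, en + L, en))
    if (hi - lo > L) stop("feature span exceeds genome length")
    return(interval(lo %% L, ((hi - 1L) %% L) + 1L, feat$parts[[1]]$strand,
                    wraps = hi > L))
  }
  interval(min(st), max(en), feat$parts[[1]]$strand)
}

# Extract the spliced, strand-corrected sequence of a feature
feature_seq <- function(record, feat) {
  pieces <- vapply(feat$parts, function(p) {
    s <- interval_seq(record$seq, p)
    if (p$strand == "-") revcomp(s) else s
  }, character(1))
  paste0(pieces, collapse = "")
}

# ---- Plastome record --------------------------------------------------------

#' Create a plastome record
#'
#' The unit every analysis stage consumes: an uppercase nucleotide sequence
#' over `{A,C,G,T,N}` plus typed gene features.
#'
#' @param id accession or label.
#' @param seq nucleotide string; coerced to uppercase.
#' @param circular logical; plastomes are circular unless stated otherwise.
#' @param features list of [gene_feature()].
#' @return A list of class `"plastome_record"`.
#' @export
plastome_record <- function(id, seq, circular = TRUE, features = list()) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(seq)
  for (f in features) for (p in f$parts) {
    if (p$start < 0 || p$end > L) stop("feature interval outside [0, length) for ", f$name)
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features\n",
              x$id, format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' Genome length of a record
#' @param record a [plastome_record()].
#' @return integer length in bp.
#' @export
genome_length <- function(record) nchar(record$seq)

#' Rotate a circular record
#'
#' Returns a record whose sequence begins at position `offset` of the input;
#' all feature coordinates are shifted accordingly (wrapping as needed).
#'
#' @param record a circular [plastome_record()].
#' @param offset 0-based position that becomes the new origin.
#' @return A rotated [plastome_record()].
#' @export
rotate_record <- function(record, offset) {
  L <- genome_length(record)
  offset <- as.integer(offset %% L)
  if (!record$circular) stop("cannot rotate a linear record")
  if (offset == 0L) return(record)
  seq2 <- paste0(substr(record$seq, offset + 1L, L), substr(record$seq, 1L, offset))
  feats <- lapply(record$features, function(f) {
    f$parts <- lapply(f$parts, function(p) {
      ns <- (p$start - offset) %% L
      ne_raw <- ns + interval_length(p, L)
      interval(ns, if (ne_raw > L) ne_raw - L else ne_raw, p$strand,
               wraps = ne_raw > L)
    })
    f
  })
  plastome_record(record$id, seq2, record$circular, feats)
}

# ---- small sequence utilities ----------------------------------------------

#' Reverse complement of a nucleotide string
#' @param s nucleotide string over `{A,C,G,T,N}`.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# normalized (case-insensitive) gene-name key
gene_key <- function(name) tolower(trimws(name))
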