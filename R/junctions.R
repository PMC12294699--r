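# Gene content at the four IR junctions (JLB, JSB, JSA, JLA).
#
# Extensions into the repeats are computed from the sequence-derived
# partition intersected with annotation coordinates: a statement like "the
# IRb extends 110 bp into rps19" is about the sequence-level IR boundary,
# not about the annotation alone.  Multi-part genes are measured on their
# genomic span (introns included), matching junction-diagram semantics.

# circular distance from a to b walking forward (a -> b), in [0, L)
circ_fwd <- function(a, b, L) (b - a) %% L

#' Gene placements around the quadripartite junctions
#'
#' For each junction, reports every gene that spans it (with the number of
#' bases on each side) or whose span lies within `window` bp of it.
#' Pseudogene fragments (e.g. the truncated ycf1 copy near JLB) are
#' included and flagged.
#'
#' @param record a [plastome_record()] with features.
#' @param partition the [detect_partition()] result for `record`.
#' @param window report genes whose nearest edge is within this many bp of
#'   a junction (default 1000).
#' @return data.frame with columns `junction`, `gene`, `pseudo`,
#'   `placement` (`"spans"`, `"within-window-left"`, `"within-window-right"`),
#'   `bp_left`, `bp_right` (bases of the gene on the upstream-/downstream-
#'   region side of the boundary; 0 unless spanning) and `distance` (bp from
#'   the nearest gene edge to the junction; 0 when spanning).
#' @export
junction_report <- function(record, partition, window = 1000L) {
  stopifnot(window >= 0L)
  L <- partition$length
  juncs <- partition$junctions
  rows <- list()
  for (jn in names(juncs)) {
    jpos <- juncs[[jn]]
    for (f in record$features) {
      sp <- feature_span(f, L)
      glen <- interval_length(sp, L)
      if (glen == 0L || glen >= L) next
      # forward distance from span start to the junction boundary
      into <- circ_fwd(sp$start, jpos, L)
      if (into > 0L && into < glen) {
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, gene = f$name, pseudo = f$pseudo,
          placement = "spans", bp_left = into, bp_right = glen - into,
          distance = 0L, stringsAsFactors = FALSE)
      } else {
        d_right <- circ_fwd(jpos, sp$start, L)            # gene begins after the junction
        d_left <- circ_fwd((sp$start + glen) %% L, jpos, L) # gene ends before it
        if (d_right <= d_left && d_right <= window) {
          rows[[length(rows) + 1L]] <- data.frame(
            junction = jn, gene = f$name, pseudo = f$pseudo,
            placement = "within-window-right", bp_left = 0L, bp_right = 0L,
            distance = d_right, stringsAsFactors = FALSE)
        } else if (d_left < d_right && d_left <= window) {
          rows[[length(rows) + 1L]] <- data.frame(
            junction = jn, gene = f$name, pseudo = f$pseudo,
            placement = "within-window-left", bp_left = 0L, bp_right = 0L,
            distance = d_left, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(junction = character(), gene = character(),
                      pseudo = logical(), placement = character(),
                      bp_left = integer(), bp_right = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Overlap between two annotated genes
#'
#' Length of the coordinate intersection of the two genes' part unions on
#' the circular sequence; 0 when disjoint (adjacent half-open intervals do
#' not overlap). When several copies of a gene exist (IR duplicates,
#' pseudo fragments), every copy pair is considered and the maximum overlap
#' is returned.
#'
#' @param record a [plastome_record()].
#' @param gene_a,gene_b gene names (case-insensitive).
#' @param pseudo_a,pseudo_b optionally restrict to pseudo (`TRUE`) or
#'   functional (`FALSE`) copies; `NA` (default) accepts either.
#' @return overlap length in bp.
#' @export
gene_overlap <- function(record, gene_a, gene_b,
                         pseudo_a = NA, pseudo_b = NA) {
  L <- genome_length(record)
  pick <- function(name, pseudo_want) {
    fs <- Filter(function(f) gene_key(f$name) == gene_key(name) &&
                   (is.na(pseudo_want) || f$pseudo == pseudo_want),
                 record$features)
    if (length(fs) == 0L) stop("gene not annotated: ", name)
    fs
  }
  fa <- pick(gene_a, pseudo_a); fb <- pick(gene_b, pseudo_b)
  best <- 0L
  for (a in fa) for (b in fb) {
    ov <- 0L
    for (pa in a$parts) for (pb in b$parts)
      ov <- ov + interval_overlap(pa, pb, L)
    best <- max(best, ov)
  }
  best
}

#' Compare junction gene content across taxa
#'
#' Tabulates per-taxon junction reports and evaluates diagnostic
#' predicates. A diagnostic is a list with `gene`, `junction` and
#' `min_extension` (bp required on the downstream-region side, i.e. the
#' gene must span the junction with at least that many bases beyond it);
#' `min_extension = 1` simply asks whether the gene pokes across.
#'
#' @param reports named list (taxon -> [junction_report()] data.frame).
#' @param diagnostics named list of predicates.
#' @return list of class `"junction_comparison"`: `table` (all reports
#'   bound with a `taxon` column) and `diagnostics` (taxon x predicate
#'   logical matrix).
#' @export
compare_junctions <- function(reports, diagnostics = list()) {
  if (length(reports) < 2L) stop("need at least two taxa")
  taxa <- names(reports)
  tab <- do.call(rbind, lapply(taxa, function(tx)
    cbind(taxon = tx, reports[[tx]], stringsAsFactors = FALSE)))
  diag <- matrix(FALSE, nrow = length(taxa), ncol = length(diagnostics),
                 dimnames = list(taxa, names(diagnostics)))
  for (dn in names(diagnostics)) {
    d <- diagnostics[[dn]]
    for (tx in taxa) {
      r <- reports[[tx]]
      hit <- r$junction == d$junction &
        tolower(r$gene) == tolower(d$gene) &
        r$placement == "spans" & r$bp_right >= d$min_extension
      diag[tx, dn] <- any(hit)
    }
  }
  structure(list(table = tab, diagnostics = diag, taxa = taxa),
            class = "junction_comparison")
}

#' @export
print.junction_comparison <- function(x, ...) {
  cat(sprintf("<junction_comparison> %d taxa, %d diagnostics\n",
              length(x$taxa), ncol(x$diagnostics)))
  if (ncol(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}
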