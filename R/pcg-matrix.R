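# Shared protein-coding gene selection and supermatrix concatenation.
#
# Alignment is external (per-gene aligned FASTA files come in); this module
# selects the genes present, non-pseudo and sane in every taxon, exports
# them for alignment, and concatenates aligned genes into a supermatrix
# with a RAxML-style partition table.

#' Select the protein-coding genes shared by all records
#'
#' The shared set is the intersection of non-pseudo PCG names across all
#' records. IR duplicates are collapsed to one representative per taxon
#' (the longest copy; ties go to the first in genome order). Genes failing
#' translation sanity (length < 3 or not divisible by 3) are excluded from
#' the intersection with per-taxon reasons.
#'
#' @param records list of [plastome_record()] (at least two).
#' @return list of class `"gene_set_selection"`: `taxa`, sorted
#'   `shared_genes`, `exclusions` (data.frame taxon/gene/reason) and
#'   `representatives` (per taxon, gene -> feature index).
#' @export
select_shared_pcgs <- function(records) {
  if (length(records) < 2L) stop("need at least two records")
  taxa <- vapply(records, `[[`, character(1), "id")
  per_tax <- list(); excl <- list()
  for (rec in records) {
    cats <- vapply(rec$features, `[[`, character(1), "category")
    pse <- vapply(rec$features, `[[`, logical(1), "pseudo")
    idx <- which(cats == "PCG" & !pse)
    keys <- vapply(rec$features[idx], function(f) gene_key(f$name), character(1))
    lens <- vapply(rec$features[idx], function(f)
      sum(vapply(f$parts, interval_length, integer(1), L = genome_length(rec))),
      integer(1))
    reps <- integer(0)
    for (k in unique(keys)) {
      cand <- idx[keys == k]
      reps[k] <- cand[which.max(lens[keys == k])]
    }
    ok <- vapply(names(reps), function(k) {
      f <- rec$features[[reps[[k]]]]
      len <- sum(vapply(f$parts, interval_length, integer(1), L = genome_length(rec)))
      len >= 3L && len %% 3L == 0L
    }, logical(1))
    for (k in names(reps)[!ok])
      excl[[length(excl) + 1L]] <- data.frame(taxon = rec$id, gene = k,
                                              reason = "length not a codon multiple",
                                              stringsAsFactors = FALSE)
    # genes pseudo-only in this taxon
    pseudo_keys <- unique(vapply(rec$features[cats == "PCG" & pse],
                                 function(f) gene_key(f$name), character(1)))
    for (k in setdiff(pseudo_keys, names(reps)))
      excl[[length(excl) + 1L]] <- data.frame(taxon = rec$id, gene = k,
                                              reason = "pseudo/absent",
                                              stringsAsFactors = FALSE)
    per_tax[[rec$id]] <- reps[ok]
  }
  shared <- Reduce(intersect, lapply(per_tax, names))
  if (length(shared) == 0L) {
    sizes <- vapply(per_tax, length, integer(1))
    stop("no protein-coding gene is shared by all taxa; most restrictive: ",
         paste(names(sort(sizes))[seq_len(min(3L, length(sizes)))], collapse = ", "))
  }
  structure(list(
    taxa = taxa, shared_genes = sort(shared),
    exclusions = if (length(excl)) do.call(rbind, excl)
                 else data.frame(taxon = character(), gene = character(),
                                 reason = character(), stringsAsFactors = FALSE),
    representatives = lapply(per_tax, function(x) x[sort(intersect(names(x), shared))])
  ), class = "gene_set_selection")
}

#' @export
print.gene_set_selection <- function(x, ...) {
  cat(sprintf("<gene_set_selection> %d taxa, %d shared PCGs, %d exclusions\n",
              length(x$taxa), length(x$shared_genes), nrow(x$exclusions)))
  invisible(x)
}

#' Export unaligned per-gene FASTA files for a shared gene set
#'
#' Writes one FASTA per shared gene with one record per taxon (header =
#' taxon label), ready for an external aligner.
#'
#' @param records the records used in [select_shared_pcgs()].
#' @param selection the selection result.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
export_gene_fastas <- function(records, selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_id <- setNames(records, vapply(records, `[[`, character(1), "id"))
  paths <- character(0)
  for (g in selection$shared_genes) {
    seqs <- vapply(selection$taxa, function(tx) {
      rec <- by_id[[tx]]
      feature_seq(rec, rec$features[[selection$representatives[[tx]][[g]]]])
    }, character(1))
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- selection$taxa
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(ss, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Concatenate aligned per-gene matrices into a supermatrix
#'
#' Rows are matched by taxon label, never by file order. Within each gene
#' all rows must be equal length, and all genes must cover the same taxon
#' set; violations are errors, never silently gap-filled.
#'
#' @param per_gene named list: gene -> named character vector (taxon ->
#'   aligned sequence) or `DNAStringSet` with taxon names. Genes are
#'   concatenated in list order.
#' @return list of class `"supermatrix"`: `taxa`, `total_length`,
#'   `partitions` (data.frame gene/start/end, 1-based inclusive) and
#'   `matrix` (taxon -> concatenated sequence).
#' @export
concatenate_alignments <- function(per_gene) {
  if (length(per_gene) == 0L) stop("no gene alignments given")
  per_gene <- lapply(per_gene, function(x) {
    if (inherits(x, "XStringSet")) setNames(as.character(x), names(x)) else x
  })
  taxa <- sort(names(per_gene[[1]]))
  if (is.null(taxa) || any(!nzchar(taxa))) stop("alignments must carry taxon names")
  for (g in names(per_gene)) {
    al <- per_gene[[g]]
    if (!setequal(names(al), taxa))
      stop("taxon mismatch in gene ", g, ": ",
           paste(union(setdiff(names(al), taxa), setdiff(taxa, names(al))),
                 collapse = ", "))
    if (length(unique(nchar(al))) != 1L)
      stop("ragged alignment in gene ", g)
  }
  lens <- vapply(per_gene, function(al) unique(nchar(al)), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  mat <- vapply(taxa, function(tx)
    paste0(vapply(per_gene, function(al) al[[tx]], character(1)), collapse = ""),
    character(1))
  structure(list(taxa = taxa, total_length = unname(ends[length(ends)]),
                 partitions = data.frame(gene = names(per_gene),
                                         start = unname(starts), end = unname(ends),
                                         stringsAsFactors = FALSE),
                 matrix = mat),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %s bp, %d partitions\n",
              length(x$taxa), format(x$total_length, big.mark = ","),
              nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix to FASTA, relaxed PHYLIP and a partition file
#'
#' @param sm a [concatenate_alignments()] result.
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.phy` and `<prefix>.partitions.txt` (RAxML-style
#'   `DNA, gene = start-end` lines).
#' @return invisible character vector of the three paths.
#' @export
write_supermatrix <- function(sm, prefix) {
  fa <- paste0(prefix, ".fasta")
  ss <- Biostrings::DNAStringSet(sm$matrix)
  names(ss) <- sm$taxa
  Biostrings::writeXStringSet(ss, fa)
  phy <- paste0(prefix, ".phy")
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(sm$taxa), sm$total_length), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$matrix[sm$taxa]), con)
  close(con)
  pt <- paste0(prefix, ".partitions.txt")
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), pt)
  invisible(c(fa, phy, pt))
}

#' Read per-gene aligned FASTA files
#' @param paths named character vector (gene -> FASTA path); unnamed paths
#'   take the file base name.
#' @return named list suitable for [concatenate_alignments()].
#' @export
read_gene_alignments <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    names(ss) <- sub("\\s.*$", "", names(ss))
    setNames(as.character(ss), names(ss))
  })
}
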