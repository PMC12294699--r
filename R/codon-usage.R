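# Codon usage: counts, RSCU, amino-acid frequencies, start-codon audits and
# the cross-taxon "significantly variable codon" (SVC) comparison.
#
# The genetic code is the bacterial/plant-plastid code (NCBI table 11).
# Its translations coincide with the standard code; the difference is the
# wider initiator set, which is why start codons are audited separately and
# alternative initiators (ACG, GTG) are counted as their sense codon.

.plastid_code <- function() Biostrings::getGeneticCode("11")

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

# synonymous families under the plastid code, stop codons separate
codon_families <- function() {
  code <- .plastid_code()
  split(names(code), unname(code))
}

#' Assemble the coding sequences of a record
#'
#' Exon parts are concatenated in transcript order with minus-strand parts
#' reverse-complemented. Pseudogenes are skipped; CDSs whose length is not
#' divisible by 3 are dropped with a warning.
#'
#' @param record a [plastome_record()].
#' @param dedupe_ir count IR-duplicated genes once (keeps the first copy in
#'   genome order). Default `FALSE`: every annotated copy counts.
#' @return named character vector of CDS sequences (names = gene symbols,
#'   possibly repeated).
#' @export
cds_sequences <- function(record, dedupe_ir = FALSE) {
  cats <- vapply(record$features, `[[`, character(1), "category")
  pse <- vapply(record$features, `[[`, logical(1), "pseudo")
  feats <- record$features[cats == "PCG" & !pse]
  if (length(feats) == 0L) stop("record ", record$id, " has no non-pseudo PCG features")
  if (dedupe_ir) {
    keys <- vapply(feats, function(f) gene_key(f$name), character(1))
    feats <- feats[!duplicated(keys)]
  }
  seqs <- vapply(feats, function(f) feature_seq(record, f), character(1))
  names(seqs) <- vapply(feats, `[[`, character(1), "name")
  bad <- nchar(seqs) %% 3L != 0L
  if (any(bad)) {
    warning("excluded CDS(s) with length not divisible by 3: ",
            paste(names(seqs)[bad], collapse = ", "))
    seqs <- seqs[!bad]
  }
  if (length(seqs) == 0L) stop("no qualifying CDS in record ", record$id)
  seqs
}

#' Count codons over the protein-coding genes of a record
#'
#' @inheritParams cds_sequences
#' @param taxon label for the resulting table (defaults to the record id).
#' @return list of class `"codon_usage_table"`: `taxon`, integer `counts`
#'   over all 64 codons (stops included), `rscu` (filled by [rscu()]),
#'   `aa_freq`, and `start_codons` (see [start_codon_inventory()]).
#' @export
count_codons <- function(record, dedupe_ir = FALSE, taxon = record$id) {
  seqs <- cds_sequences(record, dedupe_ir)
  codon_table_from_seqs(seqs, taxon)
}

#' Build a codon usage table directly from CDS strings
#' @param seqs named character vector of in-frame CDS sequences.
#' @param taxon taxon label.
#' @return a `"codon_usage_table"`.
#' @export
codon_table_from_seqs <- function(seqs, taxon = "taxon") {
  code <- .plastid_code()
  counts <- setNames(integer(64), all_codons())
  for (g in seq_along(seqs)) {
    s <- toupper(seqs[[g]])
    cods <- substring(s, seq(1, nchar(s), 3L), seq(3, nchar(s), 3L))
    internal_stop <- code[cods[-length(cods)]] == "*"
    if (any(internal_stop, na.rm = TRUE))
      warning("internal stop codon in ", names(seqs)[g])
    tab <- table(cods)
    known <- intersect(names(tab), names(counts))
    counts[known] <- counts[known] + as.integer(tab[known])
  }
  aa <- code[names(counts)]
  sense <- aa != "*"
  aa_tot <- tapply(counts[sense], aa[sense], sum)
  aa_freq <- aa_tot / sum(aa_tot)
  structure(list(taxon = taxon, counts = counts, rscu = NULL,
                 aa_freq = aa_freq,
                 start_codons = setNames(substr(toupper(seqs), 1, 3), names(seqs))),
            class = "codon_usage_table")
}

#' Relative synonymous codon usage
#'
#' For codon *i* in a synonymous family of size *k* with counts
#' `x_1..x_k`, `RSCU_i = x_i / mean(x)`. Families with zero total get
#' missing values (`NA`), never 0 or 1; stop codons carry counts but no
#' RSCU; single-codon families (Met ATG, Trp TGG) have RSCU 1 when present.
#'
#' @param table a [count_codons()] result.
#' @return the table with `rscu` filled.
#' @export
rscu <- function(table) {
  code <- .plastid_code()
  vals <- setNames(rep(NA_real_, 64), names(table$counts))
  for (fam in codon_families()) {
    aa <- code[[fam[1]]]
    if (aa == "*") next
    x <- table$counts[fam]
    tot <- sum(x)
    vals[fam] <- if (tot > 0) x / (tot / length(fam)) else NA_real_
  }
  table$rscu <- vals
  table
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %s: %d codons counted%s\n", x$taxon,
              sum(x$counts), if (is.null(x$rscu)) "" else ", RSCU filled"))
  invisible(x)
}

#' RSCU table across taxa as a data frame
#' @param tables list of RSCU-filled codon usage tables.
#' @return data.frame: codon, amino acid, then per-taxon count and RSCU
#'   columns (RSCU rounded to 2 dp).
#' @export
rscu_table <- function(tables) {
  code <- .plastid_code()
  df <- data.frame(codon = all_codons(), aa = unname(code[all_codons()]),
                   stringsAsFactors = FALSE)
  for (tb in tables) {
    df[[paste0("count_", tb$taxon)]] <- unname(tb$counts[df$codon])
    df[[paste0("rscu_", tb$taxon)]] <- round(unname(tb$rscu[df$codon]), 2)
  }
  df
}

#' Significantly variable codons across taxa
#'
#' A codon is an SVC when its usage bias differs qualitatively between
#' taxa: at least one taxon prefers it (RSCU > 1) while at least one other
#' does not (RSCU <= 1). Missing RSCU values are ignored; single-codon
#' families and stop codons never qualify. The `exclusivity` of an SVC is
#' the smaller of its two preference classes (the minority taxa); an even
#' split is flagged.
#'
#' @param tables list of at least two RSCU-filled codon usage tables.
#' @return list of class `"svc_report"`: `svc_codons`, per-codon
#'   `preference` matrix (taxon x codon, values `"preferred"`,
#'   `"unpreferred"` or `NA`), and `exclusivity` (codon -> list with
#'   `taxa` and `split` flag).
#' @export
find_svcs <- function(tables) {
  if (length(tables) < 2L) stop("need at least two taxa to compare")
  for (tb in tables) if (is.null(tb$rscu)) stop("RSCU not filled for ", tb$taxon)
  taxa <- vapply(tables, `[[`, character(1), "taxon")
  code <- .plastid_code()
  fams <- codon_families()
  multi <- unlist(fams[vapply(fams, length, integer(1)) > 1L &
                         names(fams) != "*"], use.names = FALSE)
  pref <- matrix(NA_character_, nrow = length(taxa), ncol = length(multi),
                 dimnames = list(taxa, multi))
  for (i in seq_along(tables)) {
    r <- tables[[i]]$rscu[multi]
    pref[i, ] <- ifelse(is.na(r), NA, ifelse(r > 1, "preferred", "unpreferred"))
  }
  is_svc <- apply(pref, 2L, function(col)
    any(col == "preferred", na.rm = TRUE) && any(col == "unpreferred", na.rm = TRUE))
  svc <- colnames(pref)[is_svc]
  excl <- lapply(svc, function(cd) {
    col <- pref[, cd]
    p <- taxa[!is.na(col) & col == "preferred"]
    u <- taxa[!is.na(col) & col == "unpreferred"]
    if (length(p) < length(u)) list(taxa = p, class = "preferred", split = FALSE)
    else if (length(u) < length(p)) list(taxa = u, class = "unpreferred", split = FALSE)
    else list(taxa = sort(c(p, u)), class = "split", split = TRUE)
  })
  names(excl) <- svc
  structure(list(svc_codons = svc, preference = pref, exclusivity = excl,
                 taxa = taxa),
            class = "svc_report")
}

#' @export
print.svc_report <- function(x, ...) {
  cat(sprintf("<svc_report> %d taxa, %d SVCs: %s\n", length(x$taxa),
              length(x$svc_codons), paste(x$svc_codons, collapse = " ")))
  invisible(x)
}

#' Taxa holding SVCs exclusively
#'
#' Counts, for each taxon, the SVCs whose minority class is exactly that
#' taxon (the codon singles it out against all others).
#'
#' @param report a [find_svcs()] result.
#' @return named integer vector, taxon -> number of exclusive SVCs.
#' @export
svc_exclusive_counts <- function(report) {
  out <- setNames(integer(length(report$taxa)), report$taxa)
  for (e in report$exclusivity) {
    if (!e$split && length(e$taxa) == 1L) out[e$taxa] <- out[e$taxa] + 1L
  }
  out
}

#' Start codon inventory of a record
#'
#' Maps each non-pseudo protein-coding gene to its first codon and lists
#' the genes whose start is not ATG (e.g. ACG or GTG initiators that may be
#' restored by RNA editing).
#'
#' @param record a [plastome_record()].
#' @return list with `starts` (gene -> first codon) and `non_atg`
#'   (named character vector of flagged genes).
#' @export
start_codon_inventory <- function(record) {
  seqs <- cds_sequences(record, dedupe_ir = FALSE)
  starts <- substr(seqs, 1, 3)
  list(starts = starts, non_atg = starts[starts != "ATG"])
}
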