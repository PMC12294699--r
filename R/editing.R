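# Summaries of predicted C-to-U RNA editing sites.
#
# Prediction itself is external (homology-based predictors with a
# confidence cutoff); this module consumes site tables and produces the
# per-gene, per-codon-position and per-conversion statistics used in
# comparative plastome work.  The canonical representation is sense-strand
# C -> T at the stated codon position.

.editing_cols <- c("taxon", "gene", "codon_index", "codon_pos",
                   "from_codon", "to_codon", "score")

#' Read a table of predicted RNA editing sites
#'
#' Expects a delimited file with columns `taxon`, `gene`, `codon_index`
#' (1-based codon number), `codon_pos` (1-3), `from_codon`, `to_codon`
#' and optionally `score` (predictor confidence in \[0,1\]).
#'
#' @param path TSV file path.
#' @return validated data.frame of editing sites.
#' @export
read_editing_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(.editing_cols, "score"), names(df))
  if (length(missing)) stop("editing table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  validate_editing_sites(df)
}

#' Validate editing sites against the C-to-U model
#'
#' Each site must change exactly one nucleotide, at `codon_pos`, and that
#' change must be C -> T (the sense-strand representation of C-to-U).
#'
#' @param sites data.frame of sites.
#' @return the validated data.frame (invisibly rejects nothing; invalid
#'   rows raise an error naming the first offender).
#' @export
validate_editing_sites <- function(sites) {
  for (i in seq_len(nrow(sites))) {
    fc <- toupper(sites$from_codon[i]); tc <- toupper(sites$to_codon[i])
    p <- sites$codon_pos[i]
    if (nchar(fc) != 3L || nchar(tc) != 3L || !p %in% 1:3)
      stop("invalid editing site at row ", i)
    diffs <- which(strsplit(fc, "")[[1]] != strsplit(tc, "")[[1]])
    if (!identical(diffs, as.integer(p)))
      stop("row ", i, ": codons differ at position(s) ",
           paste(diffs, collapse = ","), " but codon_pos is ", p)
    if (substr(fc, p, p) != "C" || substr(tc, p, p) != "T")
      stop("row ", i, ": not a C-to-U edit (", fc, " -> ", tc, ")")
  }
  sites
}

#' Summarize predicted RNA editing sites
#'
#' Applies the confidence cutoff, then tabulates per-gene counts, codon
#' position fractions, the amino-acid conversion matrix and the fraction
#' of sites by original amino acid. Amino acids with more than one
#' distinct conversion type (e.g. Pro -> Ser via position 1 and Pro -> Leu
#' via position 2) are flagged.
#'
#' @param sites validated editing-site data.frame.
#' @param min_score drop sites with `score < min_score` (default 0.8;
#'   sites with `NA` score are kept).
#' @return list of class `"editing_summary"`: `n_sites`, `per_gene`,
#'   `per_taxon`, `position_fractions`, `conversions` (from_aa/to_aa
#'   counts), `from_aa_fractions`, `multi_conversion_aas`.
#' @export
summarize_editing <- function(sites, min_score = 0.8) {
  validate_editing_sites(sites)
  keep <- is.na(sites$score) | sites$score >= min_score
  s <- sites[keep, , drop = FALSE]
  code <- .plastid_code()
  n <- nrow(s)
  if (n > 0L) {
    from_aa <- unname(code[toupper(s$from_codon)])
    to_aa <- unname(code[toupper(s$to_codon)])
    conv <- as.data.frame(table(from_aa = from_aa, to_aa = to_aa,
                                dnn = c("from_aa", "to_aa")),
                          stringsAsFactors = FALSE)
    conv <- conv[conv$Freq > 0, , drop = FALSE]
    names(conv)[3] <- "n"
    rownames(conv) <- NULL
    pos_frac <- as.numeric(table(factor(s$codon_pos, levels = 1:3))) / n
    from_frac <- sort(table(from_aa) / n, decreasing = TRUE)
    multi <- names(which(tapply(paste0(to_aa, "@", s$codon_pos), from_aa,
                                function(v) length(unique(v))) > 1L))
  } else {
    conv <- data.frame(from_aa = character(), to_aa = character(),
                       n = integer(), stringsAsFactors = FALSE)
    pos_frac <- rep(NA_real_, 3)
    from_frac <- table(character())
    multi <- character()
  }
  structure(list(
    n_sites = n,
    per_gene = if (n) sort(table(s$gene), decreasing = TRUE) else table(character()),
    per_taxon = if (n) table(s$taxon) else table(character()),
    position_fractions = setNames(pos_frac, c("pos1", "pos2", "pos3")),
    conversions = conv,
    from_aa_fractions = from_frac,
    multi_conversion_aas = multi,
    min_score = min_score
  ), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("<editing_summary> %d sites (score >= %s); position fractions %s\n",
              x$n_sites, format(x$min_score),
              paste(sprintf("%.3f", x$position_fractions), collapse = "/")))
  invisible(x)
}

#' Gene-by-taxon editing presence matrix
#' @param sites validated site data.frame.
#' @param min_score confidence cutoff (see [summarize_editing()]).
#' @return integer matrix gene x taxon of site counts.
#' @export
editing_presence_matrix <- function(sites, min_score = 0.8) {
  keep <- is.na(sites$score) | sites$score >= min_score
  s <- sites[keep, , drop = FALSE]
  t(table(factor(s$taxon), factor(s$gene)))
}
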