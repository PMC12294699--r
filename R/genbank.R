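# GenBank flat-file I/O.
#
# GenBank coordinates are 1-based inclusive; internal coordinates are 0-based
# half-open, converted only at this boundary.  Feature tables from different
# submitters vary; parsing is deliberately tolerant about qualifiers but
# strict about location syntax.

#' Read plastome records from a GenBank flat file
#'
#' One [plastome_record()] is returned per `LOCUS`. `join()` / `complement()`
#' locations become multi-part intervals in transcript order; `/pseudo` and
#' `/gene` qualifiers map onto the feature model. On circular records,
#' adjacent location parts that meet at the origin are coalesced into a
#' single origin-wrapping interval.
#'
#' @param path path to a GenBank flat file.
#' @return list of [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS line found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  for (k in seq_along(starts)) {
    recs[[k]] <- parse_genbank_record(lines[starts[k]:ends[k]])
  }
  recs
}

parse_genbank_record <- function(lines) {
  locus <- lines[1]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus, ignore.case = TRUE))
  # linear unless the LOCUS line says circular? plastomes default circular;
  # honour an explicit "linear", treat absent topology as circular
  if (any(grepl("linear", locus, ignore.case = TRUE))) circular <- FALSE

  ofeat <- grep("^FEATURES", lines)
  oorig <- grep("^ORIGIN", lines)
  oend <- grep("^//", lines)
  if (length(oorig) == 0L) stop("record ", id, " has no ORIGIN block")
  seq_lines <- lines[(oorig[1] + 1L):(if (length(oend)) oend[1] - 1L else length(lines))]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))

  features <- list()
  if (length(ofeat)) {
    ftab <- lines[(ofeat[1] + 1L):(oorig[1] - 1L)]
    features <- parse_feature_table(ftab, id, circular, nchar(seq))
  }
  plastome_record(id, seq, circular, features)
}

# feature keys that map onto the gene-feature model
.gb_keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", gene = NA)

parse_feature_table <- function(ftab, record_id, circular, L) {
  # group physical lines into one entry per feature key
  is_key <- grepl("^ {5}[A-Za-z'_0-9]+ ", ftab) & !grepl("^ {21}", ftab)
  idx <- cumsum(is_key)
  entries <- split(ftab[idx > 0], idx[idx > 0])

  typed <- list(); genes <- list()
  for (ent in entries) {
    key <- sub("^ {5}([A-Za-z'_0-9]+).*$", "\\1", ent[1])
    if (!key %in% names(.gb_keys)) next
    # location may continue over lines until the first qualifier line
    qual_at <- grep("^ {21}/", ent)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(ent)
    loc <- gsub("[[:space:]]", "",
                paste0(c(sub("^ {5}[A-Za-z'_0-9]+", "", ent[1]),
                         if (loc_end >= 2) trimws(ent[2:loc_end])), collapse = ""))
    quals <- parse_qualifiers(ent[seq_along(ent) > loc_end])
    name <- quals[["gene"]]
    if (is.null(name)) {
      name <- quals[["locus_tag"]]
      if (!is.null(name))
        warning("feature ", key, " at ", loc, " has no /gene; using /locus_tag ",
                name, call. = FALSE)
    }
    if (is.null(name)) next   # unnamed source/misc features
    parts <- tryCatch(parse_location(loc),
                      error = function(e) stop("record ", record_id,
                                               ": malformed location for ", key, " ",
                                               name, ": ", loc, call. = FALSE))
    parts <- coalesce_origin_parts(parts, circular, L)
    pseudo <- "pseudo" %in% names(quals) || "pseudogene" %in% names(quals)
    item <- list(key = key, name = name, parts = parts, pseudo = pseudo)
    if (key == "gene") genes[[length(genes) + 1L]] <- item
    else typed[[length(typed) + 1L]] <- item
  }

  feats <- lapply(typed, function(it) {
    gene_feature(it$name, .gb_keys[[it$key]], it$parts, it$pseudo, record_id)
  })
  # pseudo 'gene' entries with no typed counterpart become features of their
  # inferred category (trn* -> tRNA, rrn* -> rRNA, otherwise PCG)
  typed_keys <- vapply(feats, function(f) gene_key(f$name), character(1))
  for (g in genes) {
    if (!g$pseudo) next
    if (gene_key(g$name) %in% typed_keys) next
    cat_guess <- if (grepl("^trn", g$name, ignore.case = TRUE)) "tRNA"
                 else if (grepl("^rrn", g$name, ignore.case = TRUE)) "rRNA"
                 else "PCG"
    feats[[length(feats) + 1L]] <-
      gene_feature(g$name, cat_guess, g$parts, TRUE, record_id)
    typed_keys <- c(typed_keys, gene_key(g$name))
  }
  feats
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  # re-join continuation lines onto their qualifier
  starts <- grepl("^ {21}/", lines)
  idx <- cumsum(starts)
  quals <- list()
  for (chunk in split(trimws(lines)[idx > 0], idx[idx > 0])) {
    q <- paste0(chunk, collapse = "")
    m <- regmatches(q, regexec('^/([A-Za-z_0-9]+)(=("?)(.*?)\\3)?$', q, perl = TRUE))[[1]]
    if (length(m)) quals[[m[2]]] <- if (nzchar(m[3])) m[5] else TRUE
  }
  quals
}

#' Parse a GenBank location string into transcript-ordered intervals
#'
#' Supports `join()`, `order()`, `complement()` nesting, partial-end markers
#' (`<`, `>`) and single-base locations. `complement(join(...))` reverses
#' the part list so parts are always returned in transcript order.
#'
#' @param loc location string, whitespace-free.
#' @return list of [interval()].
#' @export
parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  parse_loc_node(loc, flip = FALSE)
}

parse_loc_node <- function(loc, flip) {
  if (grepl("^complement\\(", loc)) {
    inner <- strip_call(loc, "complement")
    parts <- parse_loc_node(inner, !flip)
    return(parts)
  }
  if (grepl("^(join|order)\\(", loc)) {
    fun <- sub("\\(.*$", "", loc)
    inner <- strip_call(loc, fun)
    pieces <- split_top_level(inner)
    parts <- unlist(lapply(pieces, parse_loc_node, flip = flip), recursive = FALSE)
    if (flip) parts <- rev(parts)
    return(parts)
  }
  # simple range or single base, possibly partial
  m <- regmatches(loc, regexec("^[<>]?([0-9]+)(\\.\\.[<>]?([0-9]+))?$", loc))[[1]]
  if (length(m) == 0L) stop("unparseable location: ", loc)
  a <- as.integer(m[2])
  b <- if (nzchar(m[4])) as.integer(m[4]) else a
  if (b < a) stop("descending range: ", loc)
  list(interval(a - 1L, b, if (flip) "-" else "+"))
}

strip_call <- function(loc, fun) {
  if (!endsWith(loc, ")")) stop("unbalanced location: ", loc)
  substr(loc, nchar(fun) + 2L, nchar(loc) - 1L)
}

split_top_level <- function(s) {
  depth <- 0L; out <- character(); cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

# merge transcript-adjacent parts that meet at the circular origin
coalesce_origin_parts <- function(parts, circular, L) {
  if (!circular || length(parts) < 2L) return(parts)
  out <- list(parts[[1]])
  for (p in parts[-1]) {
    q <- out[[length(out)]]
    if (q$strand == "+" && p$strand == "+" && !q$wraps && !p$wraps &&
        q$end == L && p$start == 0L) {
      out[[length(out)]] <- interval(q$start, p$end, "+", wraps = TRUE)
    } else if (q$strand == "-" && p$strand == "-" && !q$wraps && !p$wraps &&
               q$start == 0L && p$end == L) {
      out[[length(out)]] <- interval(p$start, q$end, "-", wraps = TRUE)
    } else {
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

# ---- writing ----------------------------------------------------------------

#' Write plastome records to a GenBank flat file
#'
#' The writer emits a minimal but valid flat file (LOCUS, FEATURES with
#' `source` plus every gene feature, ORIGIN). Re-reading the output restores
#' sequence, feature count and every interval exactly.
#'
#' @param records a [plastome_record()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "plastome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    L <- genome_length(rec)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
                       rec$id, L, if (rec$circular) "circular" else "linear"), con)
    writeLines(sprintf("DEFINITION  %s plastome.", rec$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    writeLines(sprintf('                     /organism="%s"', rec$id), con)
    for (f in rec$features) {
      key <- names(.gb_keys)[match(f$category, .gb_keys)]
      writeLines(sprintf("     %-15s %s", "gene", location_string(f$parts, L)), con)
      writeLines(sprintf('                     /gene="%s"', f$name), con)
      if (f$pseudo) writeLines("                     /pseudo", con)
      writeLines(sprintf("     %-15s %s", key, location_string(f$parts, L)), con)
      writeLines(sprintf('                     /gene="%s"', f$name), con)
      if (f$pseudo) writeLines("                     /pseudo", con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
      chunk <- substr(rec$seq, p, min(p + 59L, L))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

location_string <- function(parts, L) {
  rng <- function(p) {
    if (p$wraps) sprintf("%d..%d,%d..%d", p$start + 1L, L, 1L, p$end)
    else sprintf("%d..%d", p$start + 1L, p$end)
  }
  strands <- vapply(parts, `[[`, character(1), "strand")
  if (all(strands == "+")) {
    inner <- paste(vapply(parts, rng, character(1)), collapse = ",")
    if (length(parts) > 1L || parts[[1]]$wraps) paste0("join(", inner, ")") else inner
  } else if (all(strands == "-")) {
    # genomic order is the reverse of transcript order under complement(join())
    inner <- paste(vapply(rev(parts), rng, character(1)), collapse = ",")
    if (length(parts) > 1L || parts[[1]]$wraps)
      paste0("complement(join(", inner, "))")
    else paste0("complement(", inner, ")")
  } else {
    paste0("join(", paste(vapply(parts, function(p) {
      r <- rng(p); if (p$strand == "-") paste0("complement(", r, ")") else r
    }, character(1)), collapse = ","), ")")
  }
}

# ---- FASTA ------------------------------------------------------------------

#' Read sequences from a FASTA file as feature-less plastome records
#' @param path FASTA file path.
#' @param circular mark records as circular (default TRUE).
#' @return list of [plastome_record()] with empty feature lists.
#' @export
read_fasta_records <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    plastome_record(sub("\\s.*$", "", names(ss)[i]), as.character(ss[[i]]), circular)
  })
}

#' Write plastome record sequences to FASTA
#' @param records a [plastome_record()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  if (inherits(records, "plastome_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "seq"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- inventory --------------------------------------------------------------

#' Tally the gene content of a record
#'
#' Counts features by category. Under `"each-copy"` every annotated feature
#' counts once, so IR-duplicated genes count twice (the convention under
#' which plastome gene totals such as 133 = 85 + 8 + 36 + 4 balance);
#' `"unique-locus"` collapses features sharing a (case-insensitive) name.
#'
#' @param record a [plastome_record()].
#' @param mode `"each-copy"` (default) or `"unique-locus"`.
#' @return list of class `"gene_inventory"` with counts `total`, `pcg`,
#'   `trna`, `rrna`, `pseudo`, `ir_duplicated` and the `counting_mode`.
#' @export
gene_inventory <- function(record, mode = c("each-copy", "unique-locus")) {
  mode <- match.arg(mode)
  feats <- record$features
  cat_of <- vapply(feats, `[[`, character(1), "category")
  pse <- vapply(feats, `[[`, logical(1), "pseudo")
  keys <- vapply(feats, function(f) gene_key(f$name), character(1))
  dup_names <- unique(keys[duplicated(keys)])
  if (mode == "unique-locus") {
    keep <- !duplicated(keys)
    cat_of <- cat_of[keep]; pse <- pse[keep]
  }
  counts <- list(
    total = length(cat_of),
    pcg  = sum(cat_of == "PCG" & !pse),
    trna = sum(cat_of == "tRNA" & !pse),
    rrna = sum(cat_of == "rRNA" & !pse),
    pseudo = sum(pse),
    ir_duplicated = length(dup_names),
    counting_mode = mode
  )
  structure(counts, class = "gene_inventory")
}

#' @export
print.gene_inventory <- function(x, ...) {
  cat(sprintf("gene inventory (%s): total %d = %d PCG + %d rRNA + %d tRNA + %d pseudo; %d IR-duplicated\n",
              x$counting_mode, x$total, x$pcg, x$rrna, x$trna, x$pseudo,
              x$ir_duplicated))
  invisible(x)
}

#' @export
as.data.frame.gene_inventory <- function(x, ...) {
  data.frame(category = c("total", "PCG", "tRNA", "rRNA", "pseudo", "ir_duplicated"),
             count = c(x$total, x$pcg, x$trna, x$rrna, x$pseudo, x$ir_duplicated),
             stringsAsFactors = FALSE)
}
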