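# Independent brute-force oracles.  These deliberately use different
# mechanisms from the package implementations: the inverted-repeat oracle
# enumerates anti-diagonal runs of a full complementarity matrix, and the
# SSR oracle uses PCRE backreference matching.

random_dna <- function(n, gc = 0.4) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# ---- quadripartite oracle ---------------------------------------------------
# All maximal exact reverse-complement matches on a circular sequence, via
# the quadratic complementarity matrix M[i, j] = (x[i] == comp(x[j])) on the
# doubled sequence: a revcomp match is an anti-diagonal run of TRUEs.
oracle_revcomp_pairs <- function(seq, min_len) {
  n <- nchar(seq)
  x <- strsplit(paste0(seq, seq), "")[[1]]
  n2 <- 2L * n
  M <- outer(x, comp_base[x], "==")
  found <- list()
  for (s in 2:(2L * n2)) {
    i <- max(1L, s - n2):min(n2, s - 1L)
    v <- M[cbind(i, s - i)]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      l <- r$lengths[k]
      if (l < min_len) next
      i1 <- i[ends[k] - l + 1L]; i2 <- i[ends[k]]
      a <- (i1 - 1L) %% n
      b <- (s - i2 - 1L) %% n
      if (l > n %/% 2L) next
      lo <- min(a, b); hi <- max(a, b)
      found[[length(found) + 1L]] <- c(lo, hi, l)
    }
  }
  if (length(found) == 0L)
    return(data.frame(a = integer(), b = integer(), len = integer()))
  df <- unique(as.data.frame(do.call(rbind, found)))
  names(df) <- c("a", "b", "len")
  # disjointness on the circle
  keep <- vapply(seq_len(nrow(df)), function(r) {
    a <- df$a[r]; b <- df$b[r]; l <- df$len[r]
    if (a == b) return(FALSE)
    ((b - (a + l)) %% n) + ((a - (b + l)) %% n) + 2L * l == n
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# outcome of quadripartite detection under the oracle candidate set:
# list(status = "none"|"tie"|"ok", lsc, ssc, ir, junctions)
oracle_detect <- function(seq, min_ir) {
  n <- nchar(seq)
  cand <- oracle_revcomp_pairs(seq, min_ir)
  if (nrow(cand) == 0L) return(list(status = "none"))
  best <- cand[cand$len == max(cand$len), , drop = FALSE]
  if (nrow(best) > 1L) return(list(status = "tie", len = best$len[1]))
  a <- best$a[1]; b <- best$b[1]; l <- best$len[1]
  g1 <- (b - (a + l)) %% n; g2 <- (a - (b + l)) %% n
  if (g1 >= g2) {
    lsc_start <- (a + l) %% n; irb <- b; ssc_start <- (b + l) %% n
    lsc <- g1; ssc <- g2; ira <- a
  } else {
    lsc_start <- (b + l) %% n; irb <- a; ssc_start <- (a + l) %% n
    lsc <- g2; ssc <- g1; ira <- b
  }
  list(status = "ok", lsc = lsc, ssc = ssc, ir = l,
       junctions = c(JLB = irb, JSB = ssc_start, JSA = ira, JLA = lsc_start))
}

# ---- SSR oracle -------------------------------------------------------------
# Maximal primitive tandem runs via PCRE backreferences, then the shared
# reporting rules (complete units anchored at the run start, thresholds,
# earliest-start greedy overlap resolution).
oracle_scan_ssrs <- function(seq, thresholds = plastomics::ssr_default_thresholds()) {
  n <- nchar(seq)
  cand <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1+", u)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      st <- m[k]; len <- attr(m, "match.length")[k]
      # the regex is greedy in whole units but the run may extend by a
      # partial unit on the right; extend base-by-base to true maximality
      while (st + len <= n &&
             substr(seq, st + len, st + len) == substr(seq, st + len - u, st + len - u))
        len <- len + 1L
      # and ensure left-maximality (regex leftmost match guarantees it,
      # but partial-unit extension on the left is possible too)
      while (st > 1L &&
             substr(seq, st - 1L, st - 1L) == substr(seq, st - 1L + u, st - 1L + u)) {
        st <- st - 1L; len <- len + 1L
      }
      motif <- substr(seq, st, st + u - 1L)
      if (!grepl(sprintf("^[ACGT]{%d}$", u), motif)) next
      reps <- len %/% u
      if (reps < thr) next
      # primitivity
      prim <- TRUE
      for (p in seq_len(u - 1L)) {
        if (u %% p == 0L && motif == strrep(substr(motif, 1, p), u / p)) prim <- FALSE
      }
      if (!prim) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, unit_len = u, repeats = reps,
        start = st - 1L, end = st - 1L + reps * u, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(motif = character(), unit_len = integer(),
                      repeats = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, cand))
  df <- df[order(df$start, -(df$end - df$start), df$unit_len), , drop = FALSE]
  keep <- logical(nrow(df)); last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) { keep[i] <- TRUE; last_end <- df$end[i] }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- SVC oracle -------------------------------------------------------------
# exhaustive enumeration over (codon, ordered taxon pair)
oracle_svcs <- function(tables) {
  code <- Biostrings::getGeneticCode("11")
  fams <- split(names(code), unname(code))
  multi <- unlist(fams[vapply(fams, length, integer(1)) > 1 & names(fams) != "*"],
                  use.names = FALSE)
  svc <- character()
  for (cd in multi) {
    hit <- FALSE
    for (i in seq_along(tables)) for (j in seq_along(tables)) {
      ri <- tables[[i]]$rscu[[cd]]; rj <- tables[[j]]$rscu[[cd]]
      if (!is.na(ri) && !is.na(rj) && ri > 1 && rj <= 1) hit <- TRUE
    }
    if (hit) svc <- c(svc, cd)
  }
  sort(svc)
}
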