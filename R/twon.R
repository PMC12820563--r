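# Degenerate "2N motif" discovery: every 7-mer spawns the 21 patterns
# obtained by wildcarding each 2-subset of its positions; motif counts
# aggregate the 16 concrete instantiations of the two N positions; motifs
# are ranked by PD/input aggregate enrichment and classified into the two
# FoxP3 motif groups (forkhead-like G1, GCAT-core G2).

# the 21 position pairs of a 7-mer, as a 2 x 21 matrix
.POS_PAIRS <- utils::combn(7L, 2L)

#' Enumerate the 21 2N motifs of a concrete 7-mer
#'
#' Replaces each 2-subset of positions with `N`, yielding C(7,2) = 21
#' distinct degenerate patterns.
#'
#' @param seq7 a concrete 7-nt sequence.
#' @return character vector of 21 patterns.
#' @examples
#' enumerate_2n("TGTTTAC")  # includes "TGTTTNN" and "NGTTTAN"
#' @export
enumerate_2n <- function(seq7) {
  seq7 <- dna_normalize(seq7)
  if (nchar(seq7) != 7L || grepl("[^ACGT]", seq7)) {
    stop("seq7 must be a concrete 7-mer")
  }
  ch <- strsplit(seq7, "", fixed = TRUE)[[1]]
  apply(.POS_PAIRS, 2L, function(p) {
    x <- ch
    x[p] <- "N"
    paste(x, collapse = "")
  })
}

#' The 16 concrete instantiations of a 2N motif
#'
#' @param motif a 7-nt pattern with exactly two `N` positions.
#' @return character vector of the 16 concrete 7-mers it covers.
#' @export
expand_2n <- function(motif) {
  motif <- dna_normalize(motif)
  npos <- which(strsplit(motif, "", fixed = TRUE)[[1]] == "N")
  if (nchar(motif) != 7L || length(npos) != 2L) {
    stop("motif must be 7 nt with exactly two N positions")
  }
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  b <- c("A", "C", "G", "T")
  out <- character(16L)
  k <- 0L
  for (x in b) for (y in b) {
    ch[npos] <- c(x, y)
    k <- k + 1L
    out[k] <- paste(ch, collapse = "")
  }
  out
}

#' Aggregate sequence counts into 2N-motif counts
#'
#' For every distinct 2N motif reachable from the table's sequences
#' (duplicates across sequences removed), sums the counts of its 16
#' concrete instantiations.  Each sequence feeds exactly 21 motifs, so
#' total motif count equals 21 times total sequence count.
#'
#' @param tab count table with columns `sequence` and `count` (or a
#'   `count_<sample>` column named via `count_col`).
#' @param count_col name of the count column (default `"count"`).
#' @return `data.frame` with columns `motif` and `count`, sorted by motif.
#' @export
aggregate_2n_counts <- function(tab, count_col = "count") {
  cnt <- tab[[count_col]]
  if (is.null(cnt)) stop("count column '", count_col, "' not found")
  seqs <- tab$sequence
  pieces <- vector("list", ncol(.POS_PAIRS))
  for (k in seq_len(ncol(.POS_PAIRS))) {
    p <- .POS_PAIRS[, k]
    m <- seqs
    substr(m, p[1L], p[1L]) <- "N"
    substr(m, p[2L], p[2L]) <- "N"
    agg <- rowsum(cnt, group = m)
    pieces[[k]] <- data.frame(motif = rownames(agg), count = agg[, 1L],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  # motifs with different N-position pairs are distinct strings; the same
  # motif can recur only within a piece, already collapsed by rowsum
  out <- out[order(out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a 2N motif into group 1 / group 2 / other
#'
#' Group 1 (forkhead-like): the pattern's concrete positions contain the
#' substring `TGTTT` or `TGTTG`.  Group 2 (GCAT-core): the pattern
#' contains a fully concrete `GCAT` core whose flanking positions, where
#' concrete, are `T` or `C` (an `N` flank or the pattern boundary is
#' acceptable; an `N` inside the core is not).  Everything else is
#' `"other"` — wildcards never complete a core.
#'
#' @param motif character vector of 7-nt patterns over `{A,C,G,T,N}`.
#' @return character vector over `c("G1", "G2", "other")`.
#' @examples
#' classify_motif_group(c("TGTTTNN", "NNGCATN", "GCGTGCN"))
#' @export
classify_motif_group <- function(motif) {
  motif <- dna_normalize(motif)
  g1 <- grepl("TGTTT", motif, fixed = TRUE) |
    grepl("TGTTG", motif, fixed = TRUE)
  # flank acceptable when indeterminate (N or boundary) or its base set
  # is contained in {C, T} (so C, T and Y all qualify)
  flank_ok <- function(ch) {
    ch == "N" || bitwAnd(.IUPAC_BITS[[ch]], 10L) == .IUPAC_BITS[[ch]]
  }
  g2 <- vapply(motif, function(m) {
    hits <- gregexpr("GCAT", m, fixed = TRUE)[[1]]
    if (hits[1L] == -1L) return(FALSE)
    for (i in hits) {
      lf <- if (i > 1L) substr(m, i - 1L, i - 1L) else "N"
      rf <- if (i + 4L <= nchar(m)) substr(m, i + 4L, i + 4L) else "N"
      if (flank_ok(lf) && flank_ok(rf)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  ifelse(g1, "G1", ifelse(g2, "G2", "other"))
}

#' Rank 2N motifs by PD/input aggregate enrichment
#'
#' Joins the PD and input motif aggregates on the motif universe, computes
#' `count_pd / (count_input + pseudocount)`, attaches the motif group, and
#' ranks descending (ties broken lexicographically by pattern).
#'
#' @param pd,input motif aggregates from [aggregate_2n_counts()].
#' @param pseudocount raw count added to the input aggregate (default 1).
#' @return `data.frame` with columns `motif`, `group`, `count_pd`,
#'   `count_input`, `ratio`, `rank`.
#' @export
rank_2n_enrichment <- function(pd, input, pseudocount = 1) {
  m <- merge(pd, input, by = "motif", all = TRUE,
             suffixes = c("_pd", "_input"))
  m$count_pd[is.na(m$count_pd)] <- 0
  m$count_input[is.na(m$count_input)] <- 0
  m$ratio <- m$count_pd / (m$count_input + pseudocount)
  m <- m[order(-m$ratio, m$motif), , drop = FALSE]
  m$group <- classify_motif_group(m$motif)
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m[, c("motif", "group", "count_pd", "count_input", "ratio", "rank")]
}

#' Top-k motif coverage of the most enriched sequences
#'
#' Fraction of the top `decile` of sequences (by per-sequence fold
#' enrichment; the table must already carry `fold_enrichment`, see
#' [fold_enrichment()]) that match at least one of `motifs`.
#'
#' @param ranked_tab per-sequence table with `sequence` and
#'   `fold_enrichment` columns.
#' @param motifs character vector of degenerate 7-nt patterns (e.g. the
#'   top 10 ranked 2N motifs).
#' @param decile top fraction of sequences to consider (default 0.10).
#' @return the covered fraction, a number in \[0, 1\].
#' @export
motif_coverage <- function(ranked_tab, motifs, decile = 0.10) {
  o <- order(-ranked_tab$fold_enrichment, ranked_tab$sequence)
  n_top <- max(1L, floor(nrow(ranked_tab) * decile))
  top <- ranked_tab$sequence[o][seq_len(n_top)]
  hit <- rep(FALSE, n_top)
  for (m in motifs) hit <- hit | iupac_match(m, top)
  mean(hit)
}
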