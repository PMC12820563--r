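# PD-seq read extraction and count tables for the two degenerate-oligo
# library designs:
#   random-rcFKHM : site1 (7 random nt) - TCGA - GTAAACA (fixed rcFKHM)
#   random-random : site1 (7 random nt) - TCGA - site2 (7 random nt)
# Both are embedded in an 80-bp oligo between fixed non-binding flanks
# (NBS1, 27 nt; NBS2, 35 nt).

# Synthetic non-binding flanks used as package defaults.  The real flank
# sequences are experiment-specific; these stand-ins were chosen to be
# free of the TCGA spacer, FKHM-like cores (TGTTT/TGTTG and their reverse
# complements) and YGCATY cores, so they do not create spurious matches.
.DEFAULT_NBS1 <- "ACCAGACCACTCCAACTCCACCTCAAC"                  # 27 nt
.DEFAULT_NBS2 <- "CCTCCAACCACTACCTCCACCATCCACCTCACCAC"          # 35 nt

#' Degenerate-oligo template
#'
#' Describes the fixed scaffold of a PD-seq library read: constant 5'
#' flank (NBS1), a variable site 1, a fixed 4-nt spacer, a site 2 that is
#' either fixed (`"GTAAACA"`, the reverse-complement forkhead motif, for
#' the random-rcFKHM design) or variable (`NULL`, random-random design),
#' and a constant 3' flank (NBS2).
#'
#' @param nbs1 constant upstream flank (default: synthetic 27-nt
#'   non-binding sequence).
#' @param nbs2 constant downstream flank (default: synthetic 35-nt
#'   non-binding sequence).
#' @param site1_len length of variable site 1 (7).
#' @param gap fixed spacer between the sites (`"TCGA"`).
#' @param site2 fixed site-2 sequence, or `NULL` for a variable 7-nt
#'   site 2 (random-random design).
#' @param site2_len length of site 2 when variable.
#' @return an object of class `pd_template`.
#' @export
pd_template <- function(nbs1 = .DEFAULT_NBS1, nbs2 = .DEFAULT_NBS2,
                        site1_len = 7L, gap = "TCGA",
                        site2 = "GTAAACA", site2_len = 7L) {
  nbs1 <- dna_normalize(nbs1)
  nbs2 <- dna_normalize(nbs2)
  gap <- dna_normalize(gap)
  if (nchar(gap) != 4L) stop("spacer must be exactly 4 nt")
  if (!is.null(site2)) {
    site2 <- dna_normalize(site2)
    site2_len <- nchar(site2)
  }
  tpl <- list(nbs1 = nbs1, nbs2 = nbs2, site1_len = as.integer(site1_len),
              gap = gap, site2 = site2, site2_len = as.integer(site2_len))
  tpl$var_len <- tpl$site1_len + nchar(gap) + tpl$site2_len
  tpl$oligo_len <- nchar(nbs1) + tpl$var_len + nchar(nbs2)
  class(tpl) <- "pd_template"
  tpl
}

#' @export
print.pd_template <- function(x, ...) {
  design <- if (is.null(x$site2)) "random-random" else "random-rcFKHM"
  cat(sprintf("PD-seq template (%s design, %d bp oligo)\n", design, x$oligo_len))
  site2 <- if (is.null(x$site2)) strrep("N", x$site2_len) else x$site2
  cat(sprintf("  %s-[%s]-%s-[%s]-%s\n", x$nbs1, strrep("N", x$site1_len),
              x$gap, site2, x$nbs2))
  invisible(x)
}

# 1-based position of the variable region inside the full oligo
var_offset <- function(template) nchar(template$nbs1) + 1L

#' Extract variable regions from PD-seq reads
#'
#' Locates the template inside each read by exact match to the final 10 nt
#' of NBS1 and the first 10 nt of NBS2 at the expected spacing, checks the
#' fixed spacer (and fixed site 2, when the design has one), and returns
#' the variable sequence: site 1 alone (7-mer) for the random-rcFKHM
#' design, or site1+spacer+site2 (18-mer) for the random-random design.
#' Reads are rejected (counted, never raised) when a flank or fixed
#' segment fails to match exactly, when a variable position is `N`, or
#' when any variable-position Phred quality is below `min_phred`.
#'
#' @param seqs character vector of read sequences.
#' @param template a [pd_template()].
#' @param qual Phred quality strings (Sanger offset 33), or `NULL` to skip
#'   the quality filter (a warning is emitted, as for FASTA input).
#' @param min_phred per-base quality floor over the variable positions
#'   (default 20).
#' @return a list with `seq` (extracted variable sequences of the kept
#'   reads) and `rejects` (named integer vector of rejection counts:
#'   `no_anchor`, `fixed_mismatch`, `has_n`, `low_quality`).
#' @export
extract_variable_region <- function(seqs, template, qual = NULL,
                                    min_phred = 20L) {
  stopifnot(inherits(template, "pd_template"))
  if (is.null(qual)) {
    warning("no quality strings supplied; Phred filter skipped")
  } else if (length(qual) != length(seqs)) {
    stop("seqs and qual lengths differ")
  }
  seqs <- toupper(seqs)
  anchor1 <- substr(template$nbs1, nchar(template$nbs1) - 9L,
                    nchar(template$nbs1))
  anchor2 <- substr(template$nbs2, 1L, 10L)
  vlen <- template$var_len
  rejects <- c(no_anchor = 0L, fixed_mismatch = 0L, has_n = 0L,
               low_quality = 0L)

  # anchor1 position (first exact occurrence)
  a1 <- regexpr(anchor1, seqs, fixed = TRUE)
  vstart <- as.integer(a1) + 10L                     # variable region start
  ok <- a1 != -1L & (vstart + vlen + 9L) <= nchar(seqs)
  ok[ok] <- substr(seqs[ok], vstart[ok] + vlen, vstart[ok] + vlen + 9L) ==
    anchor2
  rejects["no_anchor"] <- sum(!ok)

  g0 <- vstart + template$site1_len                  # spacer start
  fixed_ok <- ok
  fixed_ok[ok] <- substr(seqs[ok], g0[ok], g0[ok] + 3L) == template$gap
  if (!is.null(template$site2)) {
    s2 <- g0 + 4L
    fixed_ok[fixed_ok] <- substr(seqs[fixed_ok], s2[fixed_ok],
                                 s2[fixed_ok] + template$site2_len - 1L) ==
      template$site2
  }
  rejects["fixed_mismatch"] <- sum(ok) - sum(fixed_ok)
  ok <- fixed_ok

  # variable (random) positions relative to vstart: site1 always; site2 too
  # in the random-random design
  rel <- seq_len(template$site1_len) - 1L
  if (is.null(template$site2)) {
    rel <- c(rel, template$site1_len + 4L + seq_len(template$site2_len) - 1L)
  }

  var7 <- substr(seqs, vstart, vstart + template$site1_len - 1L)
  varall <- substr(seqs, vstart, vstart + vlen - 1L)
  varseq <- if (is.null(template$site2)) varall else var7
  varcheck <- varseq  # positions that must be N-free

  n_ok <- ok
  n_ok[ok] <- !grepl("N", varcheck[ok], fixed = TRUE)
  rejects["has_n"] <- sum(ok) - sum(n_ok)
  ok <- n_ok

  if (!is.null(qual)) {
    idx <- which(ok)
    if (length(idx)) {
      minq <- vapply(idx, function(i) {
        q <- utf8ToInt(substr(qual[i], vstart[i], vstart[i] + vlen - 1L)) - 33L
        min(q[rel + 1L])
      }, integer(1))
      bad <- minq < min_phred
      rejects["low_quality"] <- sum(bad)
      ok[idx[bad]] <- FALSE
    }
  }

  list(seq = unname(varseq[ok]), rejects = rejects)
}

# all 4^k concrete k-mers in lexicographic order
all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  for (i in seq_len(k - 1L)) out <- as.vector(outer(out, b, paste0))
  sort(out)
}

#' Build a per-sequence count table
#'
#' Tabulates extracted variable sequences into one row per unique
#' sequence, with raw counts and RPM (reads per million kept reads) per
#' sample.  For the random-rcFKHM design (`design = "site1"`) the row
#' space is padded to all 4^7 = 16,384 concrete 7-mers with zero counts.
#'
#' @param samples named list of character vectors of extracted variable
#'   sequences (one element per sample; replicates should be concatenated
#'   before calling, i.e. combined across replicates).
#' @param design `"site1"` (7-mer rows, padded to 4^7) or `"full"`
#'   (observed 18-mer rows).
#' @return `data.frame` with column `sequence` plus `count_<sample>` and
#'   `rpm_<sample>` columns.
#' @export
build_count_table <- function(samples, design = c("site1", "full")) {
  design <- match.arg(design)
  if (is.character(samples)) samples <- list(sample = samples)
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  if (all(lengths(samples) == 0L)) warning("no reads supplied; empty table")

  rows <- if (design == "site1") {
    all_kmers(7L)
  } else {
    sort(unique(unlist(samples, use.names = FALSE)))
  }
  out <- data.frame(sequence = rows, stringsAsFactors = FALSE)
  for (nm in names(samples)) {
    tab <- table(factor(samples[[nm]], levels = rows))
    cnt <- as.integer(tab)
    tot <- sum(cnt)
    out[[paste0("count_", nm)]] <- cnt
    out[[paste0("rpm_", nm)]] <- if (tot > 0) cnt * 1e6 / tot else 0
  }
  out
}

#' Per-sequence fold enrichment (PD / input)
#'
#' Computes `rpm_pd / (rpm_input + pseudocount)` per row and returns the
#' table sorted by descending fold enrichment (ties broken
#' lexicographically by sequence, for deterministic ordering).
#'
#' @param tab a count table from [build_count_table()] containing both
#'   samples.
#' @param pd,input sample names (the table must have `rpm_<pd>` and
#'   `rpm_<input>` columns).
#' @param pseudocount RPM added to the input before division (default 0.5)
#'   so that input-zero rows stay finite.
#' @return the table with a `fold_enrichment` column, ranked descending.
#' @export
fold_enrichment <- function(tab, pd = "pd", input = "input",
                            pseudocount = 0.5) {
  rpd <- tab[[paste0("rpm_", pd)]]
  rin <- tab[[paste0("rpm_", input)]]
  if (is.null(rpd) || is.null(rin)) stop("missing rpm columns for samples")
  tab$fold_enrichment <- rpd / (rin + pseudocount)
  tab[order(-tab$fold_enrichment, tab$sequence), , drop = FALSE]
}
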