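# Genomic interval scanning for oriented pair patterns: per-Mb rates,
# exact-binomial foreground/background enrichment, gap-size sweeps, and
# merging of overlapping H-H sites.  Scanning is positive-strand only;
# matches within one pattern are non-overlapping (greedy scan) while
# overlaps between different patterns are allowed.

#' Scan interval sets for pair patterns
#'
#' Extracts the sequence of every interval from the genome and scans it
#' for each pattern with [scan_nonoverlapping()].  Matches are reported in
#' genome-absolute 0-based coordinates on the positive strand.  Matches
#' straddling an interval edge are not found (scanning is per-interval).
#'
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param ivls interval `data.frame` (peaks).
#' @param patterns pattern table from [build_pair_patterns()].
#' @return interval `data.frame` of motif sites with columns `chrom`,
#'   `start`, `end`, `strand` (always `"+"`), `motif_a`, `motif_b`,
#'   `orientation`, `gap_size`, `pattern`, `matched` (the matched genomic
#'   sequence).
#' @export
scan_intervals <- function(genome, ivls, patterns) {
  out <- vector("list", nrow(ivls))
  pm_list <- lapply(patterns$pattern, dna_encode)
  plen <- nchar(patterns$pattern)
  for (i in seq_len(nrow(ivls))) {
    chrom <- ivls$chrom[i]
    if (is.na(match(chrom, names(genome))) ||
        ivls$end[i] > nchar(genome[[chrom]])) {
      warning("interval outside contig skipped: ", chrom, ":",
              ivls$start[i], "-", ivls$end[i])
      next
    }
    seq_i <- substr(genome[[chrom]], ivls$start[i] + 1L, ivls$end[i])
    enc <- dna_encode(seq_i)
    hits <- vector("list", nrow(patterns))
    for (k in seq_len(nrow(patterns))) {
      st <- greedy_filter(match_starts_enc(pm_list[[k]], enc), plen[k])
      if (length(st)) {
        hits[[k]] <- data.frame(
          chrom = chrom,
          start = ivls$start[i] + st,
          end = ivls$start[i] + st + plen[k],
          strand = "+",
          motif_a = patterns$motif_a[k],
          motif_b = patterns$motif_b[k],
          orientation = patterns$orientation[k],
          gap_size = plen[k] - 14L,
          pattern = patterns$pattern[k],
          matched = substr(rep(seq_i, length(st)), st + 1L, st + plen[k]),
          stringsAsFactors = FALSE
        )
      }
    }
    out[[i]] <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      motif_a = character(), motif_b = character(),
                      orientation = character(), gap_size = integer(),
                      pattern = character(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact-binomial enrichment of foreground over background counts
#'
#' Rates are occurrences per million bp of the respective interval set's
#' total length.  The test conditions on the total number of occurrences
#' `n = count_fg + count_bg`; under the null, each occurrence falls in the
#' foreground with probability `p0 = len_fg / (len_fg + len_bg)`, and the
#' one-sided p-value is `P(X >= count_fg)` for `X ~ Binomial(n, p0)`.
#' Fold change is `rate_fg / rate_bg`, with a 0.5-count continuity
#' correction applied to the background only when `count_bg` is 0.
#'
#' @param count_fg,count_bg occurrence counts (vectors allowed).
#' @param len_fg,len_bg total bp of the two interval sets (must be > 0).
#' @return `data.frame` with `count_fg`, `count_bg`, `len_fg`, `len_bg`,
#'   `rate_fg`, `rate_bg` (per Mb), `fold_change`, `p_value`.
#' @export
binomial_enrichment <- function(count_fg, len_fg, count_bg, len_bg) {
  if (any(len_fg <= 0) || any(len_bg <= 0)) stop("interval lengths must be > 0")
  n <- count_fg + count_bg
  p0 <- len_fg / (len_fg + len_bg)
  p <- stats::pbinom(count_fg - 1L, n, p0, lower.tail = FALSE)
  rate_fg <- count_fg * 1e6 / len_fg
  rate_bg <- count_bg * 1e6 / len_bg
  bg_eff <- ifelse(count_bg == 0, 0.5, count_bg) * 1e6 / len_bg
  data.frame(count_fg = count_fg, count_bg = count_bg,
             len_fg = len_fg, len_bg = len_bg,
             rate_fg = rate_fg, rate_bg = rate_bg,
             fold_change = rate_fg / bg_eff,
             p_value = p)
}

total_length <- function(ivls) sum(ivls$end - ivls$start)

#' Pattern enrichment in foreground vs background interval sets
#'
#' Scans both interval sets for every pattern and runs
#' [binomial_enrichment()] per pattern.
#'
#' @inheritParams scan_intervals
#' @param fg,bg foreground (e.g. ChIP peaks) and background (e.g. open
#'   chromatin regions) interval `data.frame`s.
#' @param alpha significance threshold on the raw p-value (default 0.05,
#'   uncorrected); set `fdr = TRUE` to threshold BH-adjusted values
#'   instead.
#' @param fdr apply Benjamini-Hochberg correction before thresholding.
#' @return the pattern table with enrichment columns and a logical
#'   `significant` column.
#' @export
pattern_enrichment <- function(genome, fg, bg, patterns, alpha = 0.05,
                               fdr = FALSE) {
  sites_fg <- scan_intervals(genome, fg, patterns)
  sites_bg <- scan_intervals(genome, bg, patterns)
  cfg <- vapply(patterns$pattern,
                function(p) sum(sites_fg$pattern == p), integer(1))
  cbg <- vapply(patterns$pattern,
                function(p) sum(sites_bg$pattern == p), integer(1))
  enr <- binomial_enrichment(cfg, total_length(fg), cbg, total_length(bg))
  out <- cbind(patterns, enr)
  pv <- if (fdr) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- pv < alpha
  rownames(out) <- NULL
  out
}

#' Gap-size sweep of pair-pattern rates
#'
#' For each motif pair/orientation and each gap size, renders the pattern
#' with an `N`-wildcard gap of that size and measures the per-Mb rate in
#' the foreground and background interval sets.
#'
#' @inheritParams pattern_enrichment
#' @param pairs `data.frame` with `motif_a`, `motif_b`, `orientation`
#'   (e.g. the significantly enriched pairs).
#' @param gaps integer gap sizes to sweep (default `1:10`).
#' @return long `data.frame`: `motif_a`, `motif_b`, `orientation`, `gap`,
#'   `count_fg`, `count_bg`, `rate_fg`, `rate_bg`.
#' @export
gap_size_sweep <- function(genome, fg, bg, pairs, gaps = 1:10) {
  if (any(gaps < 1L)) stop("gap sizes must be positive")
  len_fg <- total_length(fg)
  len_bg <- total_length(bg)
  out <- vector("list", length(gaps))
  for (gi in seq_along(gaps)) {
    g <- gaps[gi]
    pat <- pairs[, c("motif_a", "motif_b", "orientation"), drop = FALSE]
    pat$gap <- strrep("N", g)
    pat$pattern <- mapply(render_pair, pat$motif_a, pat$motif_b,
                          pat$orientation, MoreArgs = list(gap = pat$gap[1L]),
                          USE.NAMES = FALSE)
    sfg <- scan_intervals(genome, fg, pat)
    sbg <- scan_intervals(genome, bg, pat)
    cfg <- vapply(pat$pattern, function(p) sum(sfg$pattern == p), integer(1))
    cbg <- vapply(pat$pattern, function(p) sum(sbg$pattern == p), integer(1))
    out[[gi]] <- data.frame(
      motif_a = pat$motif_a, motif_b = pat$motif_b,
      orientation = pat$orientation, gap = g,
      count_fg = cfg, count_bg = cbg,
      rate_fg = cfg * 1e6 / len_fg,
      rate_bg = cbg * 1e6 / len_bg,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge overlapping H-H motif sites
#'
#' H-H sites from similar motif structures often overlap; overlapping or
#' abutting sites are merged into maximal intervals to avoid duplicate
#' counting, retaining the constituent pattern identifiers.
#'
#' @param sites motif-site `data.frame` from [scan_intervals()],
#'   restricted by the caller to the H-H orientation (an error otherwise).
#' @return interval `data.frame` with `chrom`, `start`, `end`, `strand`,
#'   `n_sites` and `patterns` (comma-collapsed constituent patterns).
#' @export
merge_hh_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_sites = integer(), patterns = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(sites$orientation == "HH")) {
    stop("merge_hh_sites expects H-H sites only")
  }
  pieces <- lapply(split(sites, sites$chrom), function(s) {
    runs <- merge_runs(s$start, s$end)
    data.frame(
      chrom = s$chrom[1L],
      start = as.integer(runs$start),
      end = as.integer(runs$end),
      strand = "+",
      n_sites = lengths(runs$members),
      patterns = vapply(runs$members, function(i) {
        paste(sort(unique(s$pattern[i])), collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
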