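# TnG-repeat microsatellite detection and H-H topology: tandem arrays of
# TnG units (n = 2-5) read forward, or their CAn reverse-complement
# reading on the positive strand; spatial/orientational classification
# against merged H-H sites; coverage AUC stratification.

# Low-complexity exclusions: pure dinucleotide repeats (>= 6 units of
# TG/AC/TA/TC/AG/CG) and homopolymers (>= 12 of one base) are not valid
# TnG arrays.
.EXCLUSION_RE <- paste0(
  "^(?:(TG){6,}|(AC){6,}|(TA){6,}|(TC){6,}|(AG){6,}|(CG){6,}|",
  "T{12,}|G{12,}|C{12,}|A{12,})$"
)

#' Detect TnG-repeat arrays
#'
#' Finds maximal tandem arrays of `T{2-5}G` units (strand `"+"`; e.g.
#' `TTTGTTTG`) and of the reverse-complement `CA{2-5}` reading (strand
#' `"-"`; CAn arrays on the positive strand) in each contig.  Mixed unit
#' lengths within one array are allowed (e.g. `TTGTTTG`).  Arrays shorter
#' than `min_length` bp or with fewer than `min_units` units are
#' discarded, then the low-complexity exclusion filters are applied
#' (pure dinucleotide repeats such as (TG)x6 and >= 12-bp homopolymers are
#' removed; the unit grammar already excludes these, but the filter also
#' covers imported hit sets).
#'
#' @param genome named character vector of contig sequences, or a single
#'   unnamed sequence.
#' @param min_length minimum array length in bp (default 12).
#' @param min_units minimum number of tandem units (default 3).
#' @return interval `data.frame` with `chrom`, `start`, `end`, `strand`
#'   (`"+"` TnG reading, `"-"` CAn reading), `repeat_length` and `seq`.
#' @examples
#' detect_tng_repeats(c(chr = "CCCTTTGTTTGTTTGTTTGTTTGCCC"))
#' @export
detect_tng_repeats <- function(genome, min_length = 12L, min_units = 3L) {
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  re_plus <- sprintf("(?:T{2,5}G){%d,}", min_units)
  re_minus <- sprintf("(?:CA{2,5}){%d,}", min_units)
  pieces <- list()
  for (chrom in names(genome)) {
    s <- dna_normalize(genome[[chrom]])
    for (strand in c("+", "-")) {
      re <- if (strand == "+") re_plus else re_minus
      m <- gregexpr(re, s, perl = TRUE)[[1]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      keep <- len >= min_length
      if (!any(keep)) next
      st <- as.integer(m[keep]) - 1L
      ln <- as.integer(len[keep])
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = st + ln, strand = strand,
        repeat_length = ln,
        seq = substr(rep(s, length(st)), st + 1L, st + ln),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(pieces)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      repeat_length = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  out <- out[!grepl(.EXCLUSION_RE, out$seq, perl = TRUE), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# For each query interval, the nearest subject interval on the same
# chromosome by |signed border distance| (ties: smaller subject start).
# Returns data.frame(index = subject row or NA, distance).
nearest_feature <- function(query, subject) {
  idx <- rep(NA_integer_, nrow(query))
  dist <- rep(NA_integer_, nrow(query))
  for (i in seq_len(nrow(query))) {
    j <- which(subject$chrom == query$chrom[i])
    if (!length(j)) next
    d <- signed_border_distance(query[rep(i, length(j)), , drop = FALSE],
                                subject[j, , drop = FALSE])
    o <- order(abs(d), subject$start[j])
    idx[i] <- j[o[1L]]
    dist[i] <- d[o[1L]]
  }
  data.frame(index = idx, distance = dist)
}

#' Classify H-H / TnG-repeat topology
#'
#' For each merged H-H site, finds the nearest TnG repeat by
#' border-to-border distance (0 for overlap or abutment; positive when
#' the repeat is downstream, negative upstream), and classifies the
#' configuration: when the TnG (`"+"` strand) lies upstream of the H-H,
#' or the CAn reading (`"-"` strand) lies downstream, the repeat's
#' reading direction continues the proximal H-H half-site and the pair is
#' `"aligned"`; otherwise `"divergent"`.  For overlapping/abutting pairs
#' the side is taken from the interval midpoints.  Adjacency class is
#' `"zero_gap"` (distance 0), `"far"` (more than `far_min` bp away) or
#' `"intermediate"`.
#'
#' @param hh_sites merged H-H site intervals (see [merge_hh_sites()]).
#' @param repeats TnG repeats from [detect_tng_repeats()].
#' @param far_min distance beyond which a repeat counts as far
#'   (default 1000 bp).
#' @return `data.frame`, one row per H-H site: the site columns plus
#'   `repeat_index`, `repeat_strand`, `distance`, `configuration`
#'   (`aligned`/`divergent`) and `adjacency` (`zero_gap`/`intermediate`/
#'   `far`); sites with no same-chromosome repeat get `NA`s.
#' @export
classify_topology <- function(hh_sites, repeats, far_min = 1000L) {
  nn <- nearest_feature(hh_sites, repeats)
  out <- hh_sites
  out$repeat_index <- nn$index
  out$repeat_strand <- repeats$strand[nn$index]
  out$distance <- nn$distance
  upstream <- rep(NA, nrow(out))
  has <- !is.na(nn$index)
  if (any(has)) {
    r <- repeats[nn$index[has], , drop = FALSE]
    h <- hh_sites[has, , drop = FALSE]
    upstream[has] <- (r$start + r$end) < (h$start + h$end)
  }
  out$configuration <- ifelse(
    !has, NA_character_,
    ifelse((out$repeat_strand == "+" & upstream) |
             (out$repeat_strand == "-" & !upstream),
           "aligned", "divergent"))
  out$adjacency <- ifelse(
    !has, NA_character_,
    ifelse(out$distance == 0L, "zero_gap",
           ifelse(abs(out$distance) > far_min, "far", "intermediate")))
  out
}

#' Coverage area under the curve around feature centers
#'
#' Sums per-base coverage over `[center - halfwidth, center + halfwidth)`
#' from a bedGraph-style track.  Windows running off a contig are
#' truncated at 0 with a warning.
#'
#' @param coverage `data.frame` with `chrom`, `start`, `end`, `value`
#'   (see [read_bedgraph()]).
#' @param chrom contig name(s), recycled against `center`.
#' @param center integer window center(s), 0-based.
#' @param halfwidth window half-width in bp (default 100, i.e. a 200-bp
#'   window).
#' @return numeric vector of AUC values.
#' @export
coverage_auc <- function(coverage, chrom, center, halfwidth = 100L) {
  n <- max(length(chrom), length(center))
  chrom <- rep_len(chrom, n)
  center <- rep_len(as.integer(center), n)
  ws <- center - halfwidth
  we <- center + halfwidth
  if (any(ws < 0L)) {
    warning("window truncated at contig start")
    ws <- pmax(ws, 0L)
  }
  out <- numeric(n)
  for (ch in unique(chrom)) {
    ci <- which(chrom == ch)
    cov <- coverage[coverage$chrom == ch, , drop = FALSE]
    if (!nrow(cov)) next
    for (i in ci) {
      ov <- pmin(cov$end, we[i]) - pmax(cov$start, ws[i])
      pos <- ov > 0
      out[i] <- sum(cov$value[pos] * ov[pos])
    }
  }
  out
}

#' Stratify TnG repeats by length and H-H adjacency
#'
#' Computes each repeat's distance to the nearest H-H site, assigns a
#' length class (`short`, at most `short_max` bp; `long`, at least
#' `long_min` bp) and an adjacency class (`zero_gap`, 0-nt gap with the
#' nearest H-H; `far`, more than `far_min` bp from every H-H site;
#' intermediate distances are excluded from both classes), and attaches
#' the log2 coverage AUC (`log2(AUC + 1)`) over a 2x`halfwidth` window
#' around each repeat center.
#'
#' @param repeats TnG repeats from [detect_tng_repeats()].
#' @param hh_sites merged H-H site intervals.
#' @param coverage bedGraph-style coverage `data.frame`.
#' @param short_max,long_min length-class thresholds (defaults 20 / 40 bp).
#' @param far_min far-class distance threshold (default 1000 bp).
#' @param halfwidth AUC window half-width (default 100 bp).
#' @return `data.frame`, one row per repeat in a retained stratum:
#'   repeat columns plus `hh_distance`, `length_class`, `adjacency`,
#'   `auc`, `log2_auc`.
#' @export
stratify_repeats <- function(repeats, hh_sites, coverage,
                             short_max = 20L, long_min = 40L,
                             far_min = 1000L, halfwidth = 100L) {
  nn <- nearest_feature(repeats, hh_sites)
  dist <- nn$distance
  adjacency <- ifelse(is.na(dist), "far",          # no H-H anywhere: far
                      ifelse(dist == 0L, "zero_gap",
                             ifelse(abs(dist) > far_min, "far", NA)))
  length_class <- ifelse(repeats$repeat_length <= short_max, "short",
                         ifelse(repeats$repeat_length >= long_min, "long",
                                NA))
  keep <- !is.na(adjacency) & !is.na(length_class)
  out <- repeats[keep, , drop = FALSE]
  out$hh_distance <- dist[keep]
  out$length_class <- length_class[keep]
  out$adjacency <- adjacency[keep]
  centers <- (out$start + out$end) %/% 2L
  out$auc <- coverage_auc(coverage, out$chrom, centers, halfwidth)
  out$log2_auc <- log2(out$auc + 1)
  rownames(out) <- NULL
  out
}

#' Define binder-free open chromatin regions
#'
#' Background control set: ATAC peaks located at least `min_dist` bp from
#' every ChIP peak *and* whose ChIP coverage AUC (window around the peak
#' center) is below the minimum AUC observed across the ChIP peaks
#' themselves.
#'
#' @param atac_peaks,chip_peaks interval `data.frame`s on one assembly.
#' @param coverage ChIP coverage track (`data.frame`).
#' @param min_dist minimum distance to any ChIP peak (default 10,000 bp).
#' @param halfwidth AUC window half-width (default 100 bp).
#' @return the subset of `atac_peaks` passing both filters.
#' @export
foxp3_free_ocrs <- function(atac_peaks, chip_peaks, coverage,
                            min_dist = 10000L, halfwidth = 100L) {
  nn <- nearest_feature(atac_peaks, chip_peaks)
  far <- is.na(nn$distance) | abs(nn$distance) >= min_dist
  chip_auc <- coverage_auc(coverage, chip_peaks$chrom,
                           (chip_peaks$start + chip_peaks$end) %/% 2L,
                           halfwidth)
  atac_auc <- coverage_auc(coverage, atac_peaks$chrom,
                           (atac_peaks$start + atac_peaks$end) %/% 2L,
                           halfwidth)
  thr <- if (length(chip_auc)) min(chip_auc) else Inf
  out <- atac_peaks[far & atac_auc < thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}
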