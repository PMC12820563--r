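# Oriented paired-motif analysis of the random-random library: build the
# 400 pair patterns (10 motifs x 10 motifs x 4 orientations), count reads
# supporting each pattern with -2..+2 nt register shifts, and normalize by
# the analytic baseline probability of matching under random offsets
# (fixed spacer and flank bases bias the shifted windows).

.ORIENTATIONS <- c("HH", "HT", "TH", "TT")

render_pair <- function(a, b, orientation, gap) {
  switch(orientation,
         HH = paste0(a, gap, revcomp(b)),
         HT = paste0(a, gap, b),
         TH = paste0(revcomp(a), gap, revcomp(b)),
         TT = paste0(revcomp(a), gap, b),
         stop("unknown orientation: ", orientation))
}

#' Build oriented pair patterns
#'
#' All ordered motif pairs in the four orientations H-H, H-T, T-H, T-T.
#' Head means the motif read forward, tail its reverse complement, so the
#' rendered scan patterns are `A-gap-revcomp(B)` (H-H), `A-gap-B` (H-T),
#' `revcomp(A)-gap-revcomp(B)` (T-H) and `revcomp(A)-gap-B` (T-T).  With
#' 10 motifs this yields the 400 pair patterns (100 combinations x 4
#' orientations).  Rendered duplicates (possible for degenerate motif
#' sets) are flagged, not dropped.
#'
#' @param motifs character vector of 7-nt (possibly degenerate) motifs.
#' @param gap spacer between the half-sites: a concrete/degenerate string
#'   (default `"TCGA"`, the library spacer) or an integer gap size, which
#'   renders as that many `N` wildcards (genomic scanning).
#' @return `data.frame` with columns `motif_a`, `motif_b`, `orientation`,
#'   `gap`, `pattern` (the rendered scan pattern) and `duplicate_render`.
#' @export
build_pair_patterns <- function(motifs, gap = "TCGA") {
  motifs <- dna_normalize(motifs)
  if (any(nchar(motifs) != 7L)) stop("motifs must be 7 nt")
  if (is.numeric(gap)) gap <- strrep("N", as.integer(gap))
  gap <- dna_normalize(gap)
  grid <- expand.grid(orientation = .ORIENTATIONS, motif_b = motifs,
                      motif_a = motifs, stringsAsFactors = FALSE)
  grid <- grid[, c("motif_a", "motif_b", "orientation")]
  grid$gap <- gap
  grid$pattern <- mapply(render_pair, grid$motif_a, grid$motif_b,
                         grid$orientation, MoreArgs = list(gap = gap),
                         USE.NAMES = FALSE)
  grid$duplicate_render <- duplicated(grid$pattern)
  rownames(grid) <- NULL
  grid
}

#' Shifted windows of a variable region
#'
#' Reconstructs the full oligo around each 18-nt variable region
#' (site1 + spacer + site2) using the template's fixed flanks, and takes
#' equal-length windows at the requested register offsets.  Offset 0
#' reproduces the input; offset +1 drops the first base of site 1 and
#' appends the first base of NBS2, etc.  These shifted variants emulate
#' 0, +/-1 and +/-2 bp binding-register offsets around the central spacer.
#'
#' @param var18 character vector of variable-region sequences (length
#'   `template$var_len`).
#' @param template a [pd_template()].
#' @param offsets integer offsets (default `-2:2`, five windows per read).
#' @return a character matrix, one row per read, one column per offset
#'   (column names `"-2"` ... `"2"`).
#' @export
shifted_windows <- function(var18, template, offsets = -2:2) {
  stopifnot(inherits(template, "pd_template"))
  w <- template$var_len
  if (any(nchar(var18) != w)) stop("variable regions must be ", w, " nt")
  if (any(offsets < -nchar(template$nbs1)) ||
      any(offsets > nchar(template$nbs2))) {
    stop("offsets exceed flank lengths")
  }
  oligo <- paste0(template$nbs1, var18, template$nbs2)
  v <- var_offset(template)
  out <- vapply(offsets, function(d) substr(oligo, v + d, v + d + w - 1L),
                character(length(var18)))
  out <- matrix(out, nrow = length(var18),
                dimnames = list(NULL, as.character(offsets)))
  out
}

# Encode a vector of equal-length concrete strings into an n x m integer
# mask matrix.
encode_matrix <- function(x) {
  n <- length(x)
  m <- if (n) nchar(x[1L]) else 0L
  if (!n) return(matrix(integer(0), 0L, m))
  enc <- .IUPAC_LUT[utf8ToInt(paste(x, collapse = ""))]
  if (anyNA(enc)) stop("unsupported character in sequence")
  matrix(enc, nrow = n, ncol = m, byrow = TRUE)
}

# Encoded shifted windows of a set of variable regions: one mask matrix
# per offset, shared by counting and simulation weighting.
encode_windows <- function(vars, template, offsets = -2:2) {
  win <- shifted_windows(vars, template, offsets)
  lapply(seq_len(ncol(win)), function(k) encode_matrix(win[, k]))
}

# Rows (reads) matching a pattern at any offset.
match_any_offset <- function(encs, pattern) {
  pm <- dna_encode(pattern)
  hit <- NULL
  for (e in encs) hit <- union(hit, match_rows(e, pm))
  hit
}

# Row indices of enc (n x m masks) matched by degenerate pattern masks pm.
match_rows <- function(enc, pm) {
  idx <- seq_len(nrow(enc))
  for (j in seq_along(pm)) {
    if (pm[j] == 15L) next
    sj <- enc[idx, j]
    idx <- idx[bitwAnd(sj, pm[j]) == sj]
    if (!length(idx)) break
  }
  idx
}

#' Count reads supporting each pair pattern (any-shift semantics)
#'
#' Each read's five shifted windows are tested against every pair
#' pattern; if any shifted variant matches, the read counts once toward
#' that pattern (a read may support several distinct patterns, but never
#' the same pattern twice).  Reads are deduplicated to unique sequences
#' first and, by default, counted with their multiplicities; set
#' `unique_mode = TRUE` to count each unique sequence once.
#'
#' @param reads character vector of variable-region sequences
#'   (length `template$var_len`), one element per read.
#' @param patterns pattern table from [build_pair_patterns()].
#' @param template a [pd_template()] (random-random design).
#' @param offsets register offsets (default `-2:2`).
#' @param unique_mode count unique sequences instead of reads.
#' @return the pattern table with an added `count` column.
#' @export
count_pair_matches <- function(reads, patterns, template, offsets = -2:2,
                               unique_mode = FALSE) {
  tab <- table(reads)
  uniq <- names(tab)
  mult <- if (unique_mode) rep(1L, length(uniq)) else as.integer(tab)
  encs <- encode_windows(uniq, template, offsets)
  counts <- integer(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    hit <- match_any_offset(encs, patterns$pattern[i])
    counts[i] <- if (length(hit)) sum(mult[hit]) else 0L
  }
  patterns$count <- counts
  patterns
}

#' Analytic baseline probability of a pair pattern under random offsets
#'
#' The shifted windows overlay a mix of fixed template bases (flanks and
#' the central spacer) and uniform-random variable bases.  Per offset, the
#' match probability is the product over window positions of 1 or 0 for a
#' fixed base inside/outside the pattern's base set, and |set|/4 for a
#' random base.  The baseline is the expected number of matching offsets
#' (the sum over offsets): offsets co-match with negligible probability
#' for these patterns, and the sum is exactly computable.  Patterns whose
#' baseline is 0 (incompatible with the fixed spacer at every offset) are
#' non-normalizable.
#'
#' @param patterns pattern table from [build_pair_patterns()] (or a
#'   character vector of rendered patterns).
#' @param template a [pd_template()] (random-random design).
#' @param offsets register offsets (default `-2:2`).
#' @return numeric vector of baselines, one per pattern.
#' @export
baseline_probability <- function(patterns, template, offsets = -2:2) {
  if (is.data.frame(patterns)) patterns <- patterns$pattern
  stopifnot(inherits(template, "pd_template"))
  w <- template$var_len
  if (any(nchar(patterns) != w)) stop("patterns must be ", w, " nt")
  # mask per oligo position; NA marks a uniform-random variable position
  fixed <- dna_encode(paste0(template$nbs1, strrep("A", w), template$nbs2))
  v <- var_offset(template)
  rand_rel <- seq_len(template$site1_len) - 1L
  if (is.null(template$site2)) {
    rand_rel <- c(rand_rel,
                  template$site1_len + nchar(template$gap) +
                    seq_len(template$site2_len) - 1L)
  }
  fixed[v + rand_rel] <- NA_integer_
  gap_pos <- v + template$site1_len + seq_len(nchar(template$gap)) - 1L
  fixed[gap_pos] <- dna_encode(template$gap)
  if (!is.null(template$site2)) {
    fixed[v + template$site1_len + nchar(template$gap) +
            seq_len(template$site2_len) - 1L] <- dna_encode(template$site2)
  }

  vapply(patterns, function(p) {
    pm <- dna_encode(p)
    total <- 0
    for (d in offsets) {
      pos <- v + d + seq_len(w) - 1L
      f <- fixed[pos]
      pr <- 1
      for (j in seq_len(w)) {
        if (is.na(f[j])) {
          pr <- pr * .BITS_POP[pm[j] + 1L] / 4
        } else if (bitwAnd(pm[j], f[j]) != f[j]) {
          pr <- 0
          break
        }
      }
      total <- total + pr
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Baseline-normalized orientation matrices
#'
#' Divides each pattern's count by its analytic baseline, arranges the
#' normalized values as four motif-by-motif matrices (one per
#' orientation), scales them jointly to 0-100 for display (a single scale
#' across all four matrices, as for comparing proteins on one color
#' scale), and reports per-orientation totals of the unscaled normalized
#' values.  Non-normalizable patterns (baseline 0) are excluded with a
#' warning.
#'
#' @param counted pattern table from [count_pair_matches()] (must carry
#'   `count`).
#' @param baselines numeric baselines from [baseline_probability()], in
#'   the same pattern order.
#' @return a list with `table` (the input plus `baseline` and
#'   `normalized`), `matrices` (named list of four 10x10 display-scaled
#'   matrices) and `totals` (named numeric, sum of normalized values per
#'   orientation).
#' @export
orientation_matrix <- function(counted, baselines) {
  stopifnot(nrow(counted) == length(baselines))
  counted$baseline <- baselines
  bad <- baselines <= 0
  if (any(bad)) {
    warning(sum(bad), " non-normalizable pattern(s) excluded (baseline 0)")
  }
  counted$normalized <- ifelse(bad, NA_real_, counted$count / baselines)
  motifs <- unique(counted$motif_a)
  mx <- max(counted$normalized, na.rm = TRUE)
  scale <- if (is.finite(mx) && mx > 0) 100 / mx else 0
  mats <- lapply(.ORIENTATIONS, function(o) {
    sub <- counted[counted$orientation == o, , drop = FALSE]
    m <- matrix(NA_real_, length(motifs), length(motifs),
                dimnames = list(motifs, motifs))
    m[cbind(match(sub$motif_a, motifs), match(sub$motif_b, motifs))] <-
      sub$normalized * scale
    m
  })
  names(mats) <- .ORIENTATIONS
  totals <- vapply(.ORIENTATIONS, function(o) {
    sum(counted$normalized[counted$orientation == o], na.rm = TRUE)
  }, numeric(1))
  list(table = counted, matrices = mats, totals = totals)
}
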