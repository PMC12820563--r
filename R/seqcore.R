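# Sequence and interval primitives: IUPAC-degenerate matching, reverse
# complement, greedy non-overlapping scanning, signed border distances.
# All genomic coordinates in this package are 0-based half-open (BED
# convention); all sequences are uppercased on ingestion.

# 4-bit base masks: A=1, C=2, G=4, T=8; degenerate codes are unions.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# 256-slot lookup indexed by character code (upper and lower case).
.IUPAC_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(names(.IUPAC_BITS), collapse = ""))] <- .IUPAC_BITS
  lut[utf8ToInt(tolower(paste(names(.IUPAC_BITS), collapse = "")))] <- .IUPAC_BITS
  lut
})

# popcount of a 4-bit mask -> set cardinality
.BITS_POP <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

#' Normalize a DNA string
#'
#' Uppercases and validates a DNA string over the full IUPAC alphabet
#' (`ACGTU` plus the degenerate codes `RYSWKMBDHVN`).  Unknown characters
#' are an error.
#'
#' @param x character vector of DNA strings.
#' @return the uppercased character vector.
#' @export
dna_normalize <- function(x) {
  stopifnot(is.character(x))
  x <- toupper(x)
  bad <- grepl("[^ACGTURYSWKMBDHVN]", x)
  if (any(bad)) {
    stop("unsupported character(s) in DNA string: ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  x
}

# Encode one string as an integer mask vector (validates alphabet).
dna_encode <- function(s) {
  if (!nzchar(s)) return(integer(0))
  m <- .IUPAC_LUT[utf8ToInt(s)]
  if (anyNA(m)) stop("unsupported character in DNA string: ", s)
  m
}

#' Reverse complement with IUPAC degeneracy
#'
#' Complements every base (degenerate codes map to their complements:
#' N to N, K to M, Y to R, H to D, ...) and reverses the string.  An
#' involution: `revcomp(revcomp(s)) == s`.
#'
#' @param x character vector of DNA strings over the IUPAC alphabet.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("TGTTTAC")  # "GTAAACA"
#' revcomp("TGTTTNN")  # "NNAAACA"
#' @export
revcomp <- function(x) {
  x <- dna_normalize(x)
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Exact-length degenerate match
#'
#' Tests whether a concrete sequence lies inside the set of sequences
#' encoded by an equal-length degenerate pattern: at every position the
#' base set of `s` must be contained in the base set of `pattern`
#' (so a concrete base matches any degenerate code covering it, and an
#' `N` in `s` matches only an `N` in the pattern).
#'
#' @param pattern degenerate pattern (IUPAC), single string.
#' @param s sequence(s) of the same length as `pattern`.
#' @return logical vector, one element per sequence in `s`.
#' @examples
#' iupac_match("TGTTTNN", "TGTTTAC")  # TRUE
#' iupac_match("NNGCATY", "TTGCATC")  # TRUE (Y = C/T)
#' @export
iupac_match <- function(pattern, s) {
  stopifnot(length(pattern) == 1L)
  pattern <- dna_normalize(pattern)
  s <- dna_normalize(s)
  m <- nchar(pattern)
  if (any(nchar(s) != m)) stop("pattern and sequence lengths differ")
  pm <- dna_encode(pattern)
  n <- length(s)
  if (n == 0L) return(logical(0))
  sm <- matrix(.IUPAC_LUT[utf8ToInt(paste(s, collapse = ""))],
               nrow = n, ncol = m, byrow = TRUE)
  ok <- rep(TRUE, n)
  for (j in seq_len(m)) {
    if (pm[j] == 15L) next
    ok <- ok & (bitwAnd(sm[, j], pm[j]) == sm[, j])
  }
  ok
}

# All 0-based match start positions of a degenerate pattern in an encoded
# subject (integer mask vector).  Subset-index loop keeps cost near the
# first informative pattern position.
match_starts_enc <- function(pm, senc) {
  m <- length(pm)
  n <- length(senc) - m + 1L
  if (n <= 0L) return(integer(0))
  idx <- seq_len(n)
  for (j in seq_len(m)) {
    if (pm[j] == 15L) next
    sj <- senc[idx + (j - 1L)]
    idx <- idx[bitwAnd(sj, pm[j]) == sj]
    if (!length(idx)) return(integer(0))
  }
  idx - 1L
}

#' All degenerate match positions (0-based, possibly overlapping)
#'
#' @param pattern degenerate IUPAC pattern.
#' @param s concrete subject sequence.
#' @return integer vector of 0-based match start positions.
#' @export
match_starts <- function(pattern, s) {
  pattern <- dna_normalize(pattern)
  s <- dna_normalize(s)
  match_starts_enc(dna_encode(pattern), dna_encode(s))
}

#' Greedy non-overlapping scan
#'
#' Left-to-right scan for a degenerate pattern: after a match at position
#' `i` the search resumes at `i + nchar(pattern)`, so matches of the same
#' pattern never overlap (matches of *different* patterns may overlap; that
#' rule lives in the caller).  Prevents inflated counts from sliding
#' matches within repetitive sequence.
#'
#' @inheritParams match_starts
#' @return strictly increasing integer vector of 0-based match starts with
#'   pairwise-disjoint match windows.
#' @examples
#' scan_nonoverlapping("TTTG", "TTTGTTTGTTTG")  # 0 4 8
#' scan_nonoverlapping("TNT", "TATATAT")        # 0 3
#' @export
scan_nonoverlapping <- function(pattern, s) {
  m <- nchar(pattern)
  starts <- match_starts(pattern, s)
  greedy_filter(starts, m)
}

# Greedy left-to-right selection of non-overlapping windows of width m
# from sorted candidate starts.
greedy_filter <- function(starts, m) {
  if (length(starts) <= 1L) return(starts)
  keep <- integer(length(starts))
  k <- 0L
  nxt <- -1L
  for (p in starts) {
    if (p >= nxt) {
      k <- k + 1L
      keep[k] <- p
      nxt <- p + m
    }
  }
  keep[seq_len(k)]
}

#' Construct a genomic interval table
#'
#' Plain-data container used throughout the package: a `data.frame` with
#' columns `chrom`, `start`, `end` (0-based half-open) and `strand`
#' (`"+"`, `"-"` or `"."`).  Extra columns pass through untouched.
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors, 0-based half-open, `0 <= start < end`.
#' @param strand strand vector, recycled; defaults to `"."`.
#' @param ... further columns.
#' @return a `data.frame` of intervals.
#' @export
intervals <- function(chrom, start, end, strand = ".", ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    stop("intervals require 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, ..., stringsAsFactors = FALSE)
}

#' Signed border-to-border distance between intervals
#'
#' Distance convention for relating a feature `b` to an anchor `a`:
#' positive when `b` lies downstream of `a` (from the end of `a` to the
#' start of `b`), negative when upstream, and 0 when the two intervals
#' overlap *or* abut (the 0-nt-gap category covers sites immediately
#' adjacent to or overlapping the anchor).  Vectorized; both arguments are
#' recycled row-wise.
#'
#' @param a,b interval `data.frame`s (see [intervals()]); must be on the
#'   same chromosome row-wise.
#' @return integer vector of signed distances.
#' @export
signed_border_distance <- function(a, b) {
  if (any(a$chrom != b$chrom)) stop("intervals on different chromosomes")
  ifelse(b$start >= a$end, b$start - a$end,
         ifelse(a$start >= b$end, -(a$start - b$end), 0L))
}

# Merge overlapping or abutting intervals on one chromosome; returns
# data.frame(start, end, members = list of row indices merged).
merge_runs <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  n <- length(start)
  grp <- integer(n)
  g <- 1L
  grp[1L] <- g
  cur_end <- end[1L]
  for (i in seq_len(n)[-1L]) {
    if (start[i] > cur_end) {
      g <- g + 1L
      cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
    grp[i] <- g
  }
  data.frame(
    start = tapply(start, grp, min)[seq_len(g)],
    end = tapply(end, grp, max)[seq_len(g)],
    members = I(split(o, grp))
  )
}
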