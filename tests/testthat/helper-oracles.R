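# Independent oracles and fixture builders, deliberately naive so they
# share no code path with the implementation under test.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

rand_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# per-position set-membership match oracle
oracle_match <- function(pattern, s) {
  p <- strsplit(pattern, "")[[1]]
  x <- strsplit(s, "")[[1]]
  all(mapply(function(pc, xc) xc %in% IUPAC_SETS[[pc]], p, x))
}

# brute-force greedy non-overlapping scan oracle (0-based starts)
oracle_greedy_scan <- function(pattern, s) {
  m <- nchar(pattern)
  out <- integer(0)
  i <- 1L
  while (i + m - 1L <= nchar(s)) {
    if (oracle_match(pattern, substr(s, i, i + m - 1L))) {
      out <- c(out, i - 1L)
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  out
}

# exact binomial upper-tail oracle by direct summation of the pmf
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# reverse complement oracle via Biostrings
oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# short template with distinctive flanks for extraction tests
toy_template <- function(site2 = "GTAAACA") {
  pd_template(site2 = site2)
}

# the running example top-10 motif set (5 G1, 5 G2) used across tests
toy_top10 <- c("TGTTTNN", "NGTTTAN", "TGTTGNN", "NTGTTTN", "NNTGTTT",
               "NNGCATN", "TGCATNN", "NGCATCN", "TTGCATN", "CGCATTN")

# build a perfect read (oligo) around a given variable region
toy_read <- function(var, template = toy_template()) {
  paste0(template$nbs1, var, template$nbs2)
}

q30 <- function(read) strrep("?", nchar(read))  # Phred 30 throughout
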