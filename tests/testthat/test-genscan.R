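test_that("interval scanning recovers planted sites in absolute coordinates", {
  set.seed(81)
  contig <- rand_dna(1, 1200, alphabet = c("A", "C"))  # inert background
  substr(contig, 501, 518) <- "TGTTTACTCGAGTAAACA"
  genome <- c(chrA = contig)
  peaks <- intervals("chrA", 400, 700)
  pats <- build_pair_patterns("TGTTTNN", gap = 4)
  sites <- scan_intervals(genome, peaks, pats)
  hh <- sites[sites$orientation == "HH", ]
  expect_identical(nrow(hh), 1L)
  expect_identical(hh$start, 500L)
  expect_identical(hh$end, 518L)
  expect_identical(hh$strand, "+")
  expect_identical(hh$matched, "TGTTTACTCGAGTAAACA")
  expect_identical(hh$gap_size, 4L)

  # empty interval set
  empty <- scan_intervals(genome, peaks[0, ], pats)
  expect_identical(nrow(empty), 0L)

  # interval beyond the contig is skipped with a warning
  expect_warning(scan_intervals(genome, intervals("chrA", 1100, 1300), pats),
                 "outside contig")
})

test_that("a TnG array is read as multiple head-to-tail G1-G1 pairs with a 4-nt gap", {
  contig <- paste0(strrep("CA", 30), strrep("TTTG", 12), strrep("CA", 30))
  genome <- c(chr = contig)
  peaks <- intervals("chr", 0, nchar(contig))
  pats <- build_pair_patterns(c("TGTTTNN", "NTGTTTN"), gap = 4)
  sites <- scan_intervals(genome, peaks, pats)
  ht_g1 <- sites[sites$orientation == "HT", ]
  expect_gt(nrow(ht_g1), 1L)
  expect_true(all(ht_g1$gap_size == 4L))
})

test_that("exact binomial enrichment matches enumeration and scales correctly", {
  r <- binomial_enrichment(10, 1e6, 10, 1e6)
  expect_equal(r$fold_change, 1.0)
  expect_equal(r$p_value, oracle_binom_upper(10, 20, 0.5), tolerance = 1e-12)
  expect_equal(round(r$p_value, 3), 0.588)

  expect_equal(binomial_enrichment(0, 1e6, 5, 1e6)$p_value, 1.0)

  # doubling all inputs leaves rates and fold change unchanged
  a <- binomial_enrichment(7, 2e6, 3, 5e6)
  b <- binomial_enrichment(14, 4e6, 6, 1e7)
  expect_equal(a$rate_fg, b$rate_fg)
  expect_equal(a$rate_bg, b$rate_bg)
  expect_equal(a$fold_change, b$fold_change)

  # background-zero continuity correction keeps fold change finite
  z <- binomial_enrichment(4, 1e6, 0, 1e6)
  expect_true(is.finite(z$fold_change))
  expect_equal(z$fold_change, 4 / 0.5)

  expect_error(binomial_enrichment(1, 0, 1, 1e6), "lengths")

  # oracle equivalence across a small grid (n <= 20)
  for (cf in c(0, 1, 3, 8)) {
    for (cb in c(0, 2, 9)) {
      for (p0 in c(0.2, 0.5, 0.8)) {
        lf <- p0 * 1e6
        lb <- (1 - p0) * 1e6
        got <- binomial_enrichment(cf, lf, cb, lb)$p_value
        expect_equal(got, oracle_binom_upper(cf, cf + cb, p0),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rate normalization is invariant under splitting interval sets", {
  set.seed(82)
  contig <- rand_dna(1, 4000)
  genome <- c(chr = contig)
  pats <- build_pair_patterns("TGTTTNN", gap = 4)
  whole <- intervals("chr", 0, 4000)
  halves <- intervals("chr", c(0, 2000), c(2000, 4000))
  n_whole <- nrow(scan_intervals(genome, whole, pats))
  n_halves <- nrow(scan_intervals(genome, halves, pats))
  # only matches straddling the cut can differ; lengths are identical
  expect_identical(foxpair:::total_length(whole),
                   foxpair:::total_length(halves))
  expect_lte(abs(n_whole - n_halves), 1L)
})

test_that("gap sweep peaks at the planted gap size", {
  set.seed(83)
  contig <- rand_dna(1, 6000, alphabet = c("A", "C"))
  # plant three gap-4 instances in the foreground region
  for (s in c(500, 1500, 2500)) {
    substr(contig, s, s + 17) <- "TGTTTACTCGAGTAAACA"
  }
  genome <- c(chr = contig)
  fg <- intervals("chr", 0, 3000)
  bg <- intervals("chr", 3000, 6000)
  pairs <- data.frame(motif_a = "TGTTTNN", motif_b = "TGTTTNN",
                      orientation = "HH", stringsAsFactors = FALSE)
  sweep <- gap_size_sweep(genome, fg, bg, pairs, gaps = 1:8)
  expect_equal(sweep$gap[which.max(sweep$rate_fg)], 4)
  expect_identical(sum(sweep$count_fg[sweep$gap == 4]), 3L)
  expect_true(all(sweep$count_bg == 0L))

  # pair absent everywhere gives an all-zero row
  absent <- data.frame(motif_a = "NNGCATN", motif_b = "NNGCATN",
                       orientation = "HH", stringsAsFactors = FALSE)
  sw0 <- gap_size_sweep(genome, fg, bg, absent, gaps = 4)
  expect_true(all(sw0$count_fg == 0L) && all(sw0$count_bg == 0L))
  expect_error(gap_size_sweep(genome, fg, bg, pairs, gaps = 0:3), "positive")
})

test_that("overlapping H-H sites merge into maximal intervals", {
  sites <- data.frame(
    chrom = "chr1", start = c(100L, 110L, 300L), end = c(118L, 128L, 318L),
    strand = "+", orientation = "HH",
    pattern = c("p1", "p2", "p1"), stringsAsFactors = FALSE
  )
  merged <- merge_hh_sites(sites)
  expect_identical(nrow(merged), 2L)
  expect_identical(merged$start, c(100L, 300L))
  expect_identical(merged$end, c(128L, 318L))
  expect_identical(merged$patterns[1], "p1,p2")
  expect_lte(nrow(merged), nrow(sites))
  expect_error(merge_hh_sites(transform(sites, orientation = "HT")), "H-H")
  expect_identical(nrow(merge_hh_sites(sites[0, ])), 0L)
})

test_that("adding reverse-complement contigs symmetrizes the heatmaps", {
  set.seed(84)
  motifs <- c("TGTTTNN", "NGCATCN")
  pats <- build_pair_patterns(motifs, gap = 4)
  contig <- paste0(
    rand_dna(1, 2000),
    paste(vapply(sample(pats$pattern, 12, replace = TRUE),
                 foxpair:::instantiate_pattern, character(1)),
          collapse = strrep("C", 25)),
    rand_dna(1, 500)
  )
  genome <- c(fwd = contig, rc = revcomp(contig))
  ivls <- intervals(c("fwd", "rc"), 0, nchar(contig))
  sites <- scan_intervals(genome, ivls, pats)
  cnt <- function(a, b, o) {
    sum(sites$motif_a == a & sites$motif_b == b & sites$orientation == o)
  }
  for (a in motifs) for (b in motifs) {
    expect_identical(cnt(a, b, "HH"), cnt(b, a, "HH"))
    expect_identical(cnt(a, b, "TT"), cnt(b, a, "TT"))
    expect_identical(cnt(a, b, "HT"), cnt(b, a, "TH"))
  }
})

test_that("pattern enrichment flags the planted foreground pattern", {
  set.seed(85)
  contig <- rand_dna(1, 8000, alphabet = c("A", "C"))
  for (s in seq(200, 3800, by = 400)) {
    substr(contig, s, s + 17) <- "TGTTTACTCGAGTAAACA"
  }
  genome <- c(chr = contig)
  fg <- intervals("chr", 0, 4000)
  bg <- intervals("chr", 4000, 8000)
  pats <- build_pair_patterns("TGTTTNN", gap = 4)
  enr <- pattern_enrichment(genome, fg, bg, pats)
  hh <- enr[enr$orientation == "HH", ]
  expect_true(hh$significant)
  expect_gt(hh$fold_change, 1)
  expect_identical(hh$count_fg, 10L)
})
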