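test_that("TnG detection finds tandem arrays and applies exclusion filters", {
  # (TTTG)_5: one plus-strand repeat of 20 bp (a "short"-class array)
  r <- detect_tng_repeats(c(chr = paste0("CC", strrep("TTTG", 5), "CC")))
  expect_identical(nrow(r), 1L)
  expect_identical(r$strand, "+")
  expect_identical(r$repeat_length, 20L)
  expect_identical(r$start, 2L)

  # (TG)_6 is a dinucleotide repeat (unit T1G), not a TnG array
  expect_identical(nrow(detect_tng_repeats(c(chr = "TGTGTGTGTGTG"))), 0L)
  # homopolymers are not TnG arrays
  expect_identical(nrow(detect_tng_repeats(c(chr = strrep("T", 12)))), 0L)
  expect_identical(nrow(detect_tng_repeats(c(chr = strrep("A", 20)))), 0L)

  # mixed unit lengths within one array are allowed (n = 2-5)
  r <- detect_tng_repeats(c(chr = paste0("AA", "TTG", "TTTTG", "TTTG", "AA")))
  expect_identical(nrow(r), 1L)
  expect_identical(r$repeat_length, 12L)
  expect_identical(r$seq, "TTGTTTTGTTTG")  # the maximal mixed-unit array
})

test_that("CAn arrays are reported on the minus strand and mirror under revcomp", {
  s <- paste0("GG", strrep("CAAA", 6), "GG")
  r <- detect_tng_repeats(c(chr = s))
  expect_identical(nrow(r), 1L)
  expect_identical(r$strand, "-")
  expect_identical(r$repeat_length, 24L)

  # mirrored coordinates with flipped strand on the reverse complement
  fwd <- paste0("CCC", strrep("TTTG", 5), strrep("G", 40))
  f <- detect_tng_repeats(c(chr = fwd))
  b <- detect_tng_repeats(c(chr = revcomp(fwd)))
  expect_identical(nrow(f), nrow(b))
  expect_identical(b$strand, chartr("+-", "-+", f$strand))
  expect_identical(b$start, nchar(fwd) - f$end)
  expect_identical(b$end, nchar(fwd) - f$start)

  # min_length / min_units floors
  expect_identical(nrow(detect_tng_repeats(c(chr = "AATTTGTTTGAA"))), 0L)
  expect_identical(
    nrow(detect_tng_repeats(c(chr = "AATTTGTTTGAA"), min_length = 8L,
                            min_units = 2L)), 1L)
})

test_that("mixed-unit array detection is robust inside random background", {
  set.seed(91)
  bg <- rand_dna(1, 400, alphabet = c("A", "G"))
  s <- paste0(substr(bg, 1, 200), strrep("TTG", 8), substr(bg, 201, 400))
  r <- detect_tng_repeats(c(chr = s))
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 200L)
  expect_identical(r$repeat_length, 24L)
})

test_that("topology classification applies the aligned/divergent strand-side rule", {
  hh <- intervals("chr", c(1000L, 3000L, 5000L, 7000L),
                  c(1018L, 3018L, 5018L, 7018L), strand = "+")
  reps <- data.frame(
    chrom = "chr",
    start = c(980L, 3018L, 5040L, 6960L),
    end = c(1000L, 3038L, 5060L, 6980L),
    strand = c("+", "-", "+", "-"),
    repeat_length = 20L, stringsAsFactors = FALSE
  )
  topo <- classify_topology(hh, reps)
  # + repeat abutting upstream: distance 0, aligned
  expect_identical(topo$distance[1], 0L)
  expect_identical(topo$configuration[1], "aligned")
  # - (CAn) repeat abutting downstream: distance 0, aligned
  expect_identical(topo$distance[2], 0L)
  expect_identical(topo$configuration[2], "aligned")
  # + repeat downstream: divergent
  expect_identical(topo$distance[3], 22L)
  expect_identical(topo$configuration[3], "divergent")
  # - repeat upstream: divergent
  expect_identical(topo$distance[4], -20L)
  expect_identical(topo$configuration[4], "divergent")
  expect_identical(topo$adjacency, c("zero_gap", "zero_gap",
                                     "intermediate", "intermediate"))

  # H-H on a chromosome without repeats gets NA records
  hh2 <- rbind(hh, intervals("chrX", 10L, 28L, strand = "+"))
  topo2 <- classify_topology(hh2, reps)
  expect_true(is.na(topo2$repeat_index[5]))
  expect_true(is.na(topo2$configuration[5]))
})

test_that("planted signed offsets are recovered exactly in the distance histogram", {
  offs <- c(-50L, 0L, 50L)
  hh <- intervals("chr", c(1000L, 5000L, 9000L), c(1018L, 5018L, 9018L))
  reps <- data.frame(chrom = "chr", strand = "+", repeat_length = 20L,
                     start = c(1000L - 18L - 50L - 20L + 18L, 5018L, 9068L),
                     stringsAsFactors = FALSE)
  # construct starts so border distances are exactly -50, 0, +50
  reps$start <- c(1000L - 50L - 20L, 4998L, 9068L)
  reps$end <- reps$start + 20L
  topo <- classify_topology(hh, reps)
  expect_identical(sort(topo$distance), offs)
})

test_that("coverage AUC integrates the window and truncates at contig start", {
  cov <- data.frame(chrom = "chr", start = 0L, end = 10000L, value = 2.0)
  expect_equal(coverage_auc(cov, "chr", 5000L), 400)
  expect_equal(coverage_auc(cov[0, ], "chr", 5000L), 0)
  expect_warning(a <- coverage_auc(cov, "chr", 50L), "truncated")
  expect_equal(a, 2 * 150)
  # a centered triangular peak beats an off-center one of equal area
  tri <- data.frame(chrom = "chr",
                    start = 4900:5099, end = 4901:5100,
                    value = 5 * (1 - abs(4900:5099 + 0.5 - 5000) / 100))
  expect_gt(coverage_auc(tri, "chr", 5000L), coverage_auc(tri, "chr", 5120L))
})

test_that("repeat stratification separates boosted zero-gap repeats", {
  hh <- intervals("chr", c(1000L, 6000L), c(1018L, 6018L))
  reps <- data.frame(
    chrom = "chr",
    start = c(980L, 5952L, 20000L, 30000L),
    end = c(1000L, 6000L, 20020L, 30048L),
    strand = "+",
    repeat_length = c(20L, 48L, 20L, 48L),
    stringsAsFactors = FALSE
  )
  centers <- (reps$start + reps$end) %/% 2L
  boost <- c(100, 100, 1, 1)  # coverage boosted only at zero-gap repeats
  cov <- do.call(rbind, lapply(seq_along(centers), function(i) {
    data.frame(chrom = "chr", start = centers[i] - 50L,
               end = centers[i] + 50L, value = boost[i])
  }))
  strata <- stratify_repeats(reps, hh, cov)
  expect_identical(nrow(strata), 4L)
  for (lc in c("short", "long")) {
    z <- strata$log2_auc[strata$length_class == lc &
                           strata$adjacency == "zero_gap"]
    f <- strata$log2_auc[strata$length_class == lc &
                           strata$adjacency == "far"]
    expect_gt(median(z), median(f))
  }

  # equal coverage: strata medians coincide
  cov_eq <- transform(cov, value = 3)
  s_eq <- stratify_repeats(reps, hh, cov_eq)
  expect_equal(median(s_eq$log2_auc[s_eq$adjacency == "zero_gap"]),
               median(s_eq$log2_auc[s_eq$adjacency == "far"]))

  # intermediate distances and lengths are excluded
  reps_mid <- data.frame(chrom = "chr", start = 1500L, end = 1530L,
                         strand = "+", repeat_length = 30L,
                         stringsAsFactors = FALSE)
  expect_identical(nrow(stratify_repeats(reps_mid, hh, cov)), 0L)
})

test_that("binder-free OCRs require both distance and signal filters", {
  chip <- intervals("chr", 100000L, 100600L)
  cov <- data.frame(chrom = "chr", start = 100000L, end = 100600L,
                    value = 5.0)
  atac <- intervals("chr", c(104000L, 150000L, 200000L),
                    c(104600L, 150600L, 200600L))
  # give the third ATAC peak ChIP signal above the ChIP minimum
  cov <- rbind(cov, data.frame(chrom = "chr", start = 200000L,
                               end = 200600L, value = 50.0))
  free <- foxp3_free_ocrs(atac, chip, cov)
  expect_identical(free$start, 150000L)  # 5 kb peak and hot peak excluded
})
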