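test_that("pair patterns render the four orientations over all pairs", {
  pats <- build_pair_patterns(c("TGTTTNN", "NNGCATN"), gap = "TCGA")
  expect_identical(nrow(pats), 16L)  # 2 x 2 x 4
  hh <- pats$pattern[pats$motif_a == "TGTTTNN" & pats$motif_b == "TGTTTNN" &
                       pats$orientation == "HH"]
  expect_identical(hh, "TGTTTNNTCGANNAAACA")

  pats10 <- build_pair_patterns(toy_top10, gap = "TCGA")
  expect_identical(nrow(pats10), 400L)
  expect_identical(nrow(unique(pats10[, c("motif_a", "motif_b")])), 100L)
  expect_true(all(nchar(pats10$pattern) == 18L))

  # algebraic identity for the palindromic spacer:
  # HH(a, b) render is the reverse complement of HH(b, a) render
  for (a in toy_top10[c(1, 4, 6)]) {
    for (b in toy_top10[c(2, 7, 9)]) {
      r_ab <- pats10$pattern[pats10$motif_a == a & pats10$motif_b == b &
                               pats10$orientation == "HH"]
      r_ba <- pats10$pattern[pats10$motif_a == b & pats10$motif_b == a &
                               pats10$orientation == "HH"]
      expect_identical(r_ab, revcomp(r_ba))
    }
  }

  # integer gap renders as N wildcards
  g4 <- build_pair_patterns("TGTTTNN", gap = 4)
  expect_true(all(grepl("NNNN", g4$pattern, fixed = TRUE)))
  expect_error(build_pair_patterns("TGTTT"), "7 nt")
})

test_that("shifted windows reproduce string-slicing on the full oligo", {
  tpl <- pd_template(site2 = NULL)
  var <- paste0("TGTTTAC", "TCGA", "GCGCATC")
  win <- shifted_windows(var, tpl)
  expect_identical(dim(win), c(1L, 5L))
  expect_identical(unname(win[1, "0"]), var)
  # string-slicing oracle on the reconstructed 80-mer
  oligo <- paste0(tpl$nbs1, var, tpl$nbs2)
  v <- nchar(tpl$nbs1) + 1L
  for (d in -2:2) {
    expect_identical(unname(win[1, as.character(d)]),
                     substr(oligo, v + d, v + d + 17L))
  }
  # offset +1 drops the first base of site 1, appends NBS2's first base
  expect_identical(unname(win[1, "1"]),
                   paste0(substr(var, 2, 18), substr(tpl$nbs2, 1, 1)))
})

test_that("any-shift pair counting counts each read at most once per pattern", {
  tpl <- pd_template(site2 = NULL)
  pats <- build_pair_patterns(toy_top10, gap = "TCGA")
  read <- "TGTTTACTCGAGTAAACA"
  cnt <- count_pair_matches(read, pats, tpl)
  # brute-force: every pattern matching any of the 5 windows gets 1
  win <- shifted_windows(read, tpl)
  want <- vapply(pats$pattern, function(p) {
    as.integer(any(vapply(win[1, ], function(w) iupac_match(p, w),
                          logical(1))))
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(cnt$count, want)
  # the canonical inverted-repeat is among the supported patterns
  expect_identical(
    cnt$count[cnt$motif_a == "TGTTTNN" & cnt$motif_b == "TGTTTNN" &
                cnt$orientation == "HH"], 1L)
  # a matching read may support several patterns, never the same one twice
  dup_off <- count_pair_matches(read, pats, tpl, offsets = c(0L, 0L))
  expect_true(all(dup_off$count <= 1L))

  # non-matching read contributes nothing
  cnt0 <- count_pair_matches("ACCACCACCACCACCACC", pats, tpl)
  expect_true(all(cnt0$count == 0L))

  # multiplicity vs unique-sequence counting
  cnt3 <- count_pair_matches(rep(read, 3), pats, tpl)
  expect_identical(cnt3$count, 3L * cnt$count)
  cntu <- count_pair_matches(rep(read, 3), pats, tpl, unique_mode = TRUE)
  expect_identical(cntu$count, cnt$count)
})

test_that("strand-flipped reads exchange HH(a,b) with HH(b,a) and HT with TH", {
  tpl <- pd_template(site2 = NULL)
  motifs <- c("TGTTTNN", "NGCATCN")
  pats <- build_pair_patterns(motifs, gap = "TCGA")
  set.seed(51)
  reads <- c(rand_dna(300, 18),
             vapply(sample(pats$pattern, 40, replace = TRUE),
                    foxpair:::instantiate_pattern, character(1),
                    USE.NAMES = FALSE))
  fwd <- count_pair_matches(reads, pats, tpl, offsets = 0L)
  rev <- count_pair_matches(revcomp(reads), pats, tpl, offsets = 0L)
  key <- function(x, a, b, o) {
    x$count[x$motif_a == a & x$motif_b == b & x$orientation == o]
  }
  for (a in motifs) for (b in motifs) {
    expect_identical(key(rev, a, b, "HH"), key(fwd, b, a, "HH"))
    expect_identical(key(rev, a, b, "TT"), key(fwd, b, a, "TT"))
    expect_identical(key(rev, a, b, "HT"), key(fwd, b, a, "TH"))
    expect_identical(key(rev, a, b, "TH"), key(fwd, b, a, "HT"))
  }
})

test_that("baseline probabilities match closed forms and Monte-Carlo", {
  tpl <- pd_template(site2 = NULL)
  # fully-N pattern matches every window: per-offset 1, baseline 5
  expect_equal(baseline_probability(strrep("N", 18), tpl), 5)
  # offset 0 only: spacer fixed-fixed factor is 1, ten concrete site
  # positions each contribute 1/4
  ir <- "TGTTTNNTCGANNAAACA"
  expect_equal(baseline_probability(ir, tpl, offsets = 0L), (1 / 4) ^ 10)

  # Monte-Carlo cross-check with a high-probability degenerate pattern
  pat <- "NNGNNNNTCGANNNCNNN"
  set.seed(61)
  draws <- paste0(rand_dna(20000, 7), "TCGA", rand_dna(20000, 7))
  win <- shifted_windows(draws, tpl)
  n_match <- rowSums(vapply(seq_len(ncol(win)),
                            function(k) iupac_match(pat, win[, k]),
                            logical(nrow(win))))
  mc <- mean(n_match)
  se <- stats::sd(n_match) / sqrt(length(n_match))
  expect_lt(abs(mc - baseline_probability(pat, tpl)), 3 * se + 1e-9)

  # a pattern incompatible with the fixed spacer at every offset
  expect_equal(baseline_probability("NNNNNNNGGGGNNNNNNN", tpl), 0)
})

test_that("orientation matrices normalize, scale jointly, and stay flat under the null", {
  tpl <- pd_template(site2 = NULL)
  pats <- build_pair_patterns(c("NNGNNNN", "NNNCNNN"), gap = "TCGA")
  set.seed(71)
  reads <- paste0(rand_dna(20000, 7), "TCGA", rand_dna(20000, 7))
  cnt <- count_pair_matches(reads, pats, tpl)
  bl <- baseline_probability(pats, tpl)
  om <- orientation_matrix(cnt, bl)
  norm <- om$table$normalized
  expect_lt(stats::sd(norm) / mean(norm), 0.2)  # flat within sampling error
  expect_equal(max(unlist(om$matrices), na.rm = TRUE), 100)

  # all-zero counts give all-zero matrices
  cnt0 <- cnt
  cnt0$count <- 0L
  om0 <- orientation_matrix(cnt0, bl)
  expect_true(all(unlist(om0$matrices) == 0))
  expect_true(all(om0$totals == 0))

  # non-normalizable patterns are excluded with a warning
  bl2 <- bl
  bl2[1] <- 0
  expect_warning(om2 <- orientation_matrix(cnt, bl2), "non-normalizable")
  expect_true(is.na(om2$table$normalized[1]))
})
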