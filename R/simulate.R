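# Seeded synthetic-data generators with planted ground truth: PD-seq read
# pairs (input / pull-down) under a configurable binder model, and a
# synthetic genome bundle (FASTA sequence, peak BEDs, planted H-H and TnG
# feature BEDs, peak-shaped coverage, DE gene table) for recovery tests.

#' Binder selectivity model for PD-seq simulation
#'
#' Abstracts a protein's sequence preference in the pull-down: each read's
#' selection weight is `noise_floor` plus the summed weights of all
#' matching patterns.  Three kinds of weight map are supported: fixed-
#' register site-1 patterns (7 nt), fixed-register site-2 patterns (7 nt,
#' e.g. a monomeric binder that engages only the rcFKHM in site 2 —
#' constant on the random-rcFKHM design, hence flat site-1 enrichment),
#' and full-length pair patterns matched against the five register-shifted
#' windows (any-shift).  `pair_motifs` with `orientation_weights` is a
#' convenience that expands into pair-pattern weights via
#' [build_pair_patterns()] with the library spacer.
#'
#' @param mode `"dimeric_pair"`, `"monomeric_site2"` or `"uniform"`
#'   (uniform ignores all weights and reduces to equal sampling).
#' @param site1_weights named numeric: 7-nt degenerate pattern -> weight.
#' @param site2_weights named numeric: 7-nt degenerate pattern -> weight,
#'   applied to the site-2 slice.
#' @param pair_weights named numeric: full-length (18-nt) rendered pattern
#'   -> weight, any-shift matched.
#' @param pair_motifs optional motif vector expanded with
#'   `orientation_weights` into `pair_weights`.
#' @param orientation_weights named numeric over `HH`, `HT`, `TH`, `TT`.
#' @param noise_floor baseline weight of a non-matching read (default 1).
#' @return an object of class `binder_model`.
#' @export
binder_model <- function(mode = c("dimeric_pair", "monomeric_site2",
                                  "uniform"),
                         site1_weights = NULL, site2_weights = NULL,
                         pair_weights = NULL, pair_motifs = NULL,
                         orientation_weights = NULL, noise_floor = 1) {
  mode <- match.arg(mode)
  chk <- function(w) {
    if (!is.null(w) && (is.null(names(w)) || any(w < 0))) {
      stop("weight maps must be named and non-negative")
    }
    w
  }
  if (!is.null(pair_motifs)) {
    if (is.null(orientation_weights)) {
      stop("pair_motifs requires orientation_weights")
    }
    pat <- build_pair_patterns(pair_motifs, gap = "TCGA")
    pat <- pat[!pat$duplicate_render, , drop = FALSE]
    ow <- orientation_weights[pat$orientation]
    extra <- stats::setNames(as.numeric(ow), pat$pattern)
    extra <- extra[extra > 0]
    pair_weights <- c(pair_weights, extra)
  }
  structure(list(mode = mode,
                 site1_weights = chk(site1_weights),
                 site2_weights = chk(site2_weights),
                 pair_weights = chk(pair_weights),
                 noise_floor = noise_floor),
            class = "binder_model")
}

# selection weight of each variable-region sequence under the model
binding_weight <- function(vars, model, template) {
  n <- length(vars)
  w <- rep(model$noise_floor, n)
  if (model$mode == "uniform" || n == 0L) return(w)
  s1 <- substr(vars, 1L, template$site1_len)
  s2_from <- template$site1_len + nchar(template$gap) + 1L
  s2 <- substr(vars, s2_from, template$var_len)
  for (p in names(model$site1_weights)) {
    w <- w + model$site1_weights[[p]] * iupac_match(p, s1)
  }
  for (p in names(model$site2_weights)) {
    w <- w + model$site2_weights[[p]] * iupac_match(p, s2)
  }
  if (length(model$pair_weights)) {
    encs <- encode_windows(vars, template)
    for (p in names(model$pair_weights)) {
      hit <- match_any_offset(encs, p)
      if (length(hit)) w[hit] <- w[hit] + model$pair_weights[[p]]
    }
  }
  w
}

random_kmers <- function(n, k, base_probs = rep(0.25, 4)) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE,
                     prob = base_probs), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate PD-seq input and pull-down reads
#'
#' Draws an input pool of full-length oligo reads with uniform variable
#' positions, then samples the pull-down library from that pool with
#' replacement, with acceptance probability proportional to the binder
#' model's weight (a single selection round).  Deterministic under
#' `seed`; qualities are constant Q30 by default.
#'
#' @param template a [pd_template()].
#' @param model a [binder_model()].
#' @param n_reads reads per library.
#' @param seed integer seed.
#' @param quality constant Phred quality of every base (default 30).
#' @return a list with `input` and `pd` (character vectors of full oligo
#'   reads), `qual` (quality string, recycled per read), `var_input` and
#'   `var_pd` (the variable-region sequences).
#' @export
sim_pdseq_reads <- function(template, model, n_reads, seed,
                            quality = 30L) {
  stopifnot(inherits(template, "pd_template"),
            inherits(model, "binder_model"), n_reads > 0)
  set.seed(seed)
  s1 <- random_kmers(n_reads, template$site1_len)
  s2 <- if (is.null(template$site2)) {
    random_kmers(n_reads, template$site2_len)
  } else {
    rep(template$site2, n_reads)
  }
  vars <- paste0(s1, template$gap, s2)
  uniq <- unique(vars)
  wu <- binding_weight(uniq, model, template)
  w <- wu[match(vars, uniq)]
  pd_idx <- sample.int(n_reads, n_reads, replace = TRUE, prob = w)
  oligos <- paste0(template$nbs1, vars, template$nbs2)
  list(input = oligos,
       pd = oligos[pd_idx],
       qual = strrep(intToUtf8(33L + quality), template$oligo_len),
       var_input = vars,
       var_pd = vars[pd_idx])
}

#' Default synthetic-genome configuration
#'
#' The generator's study conditions: a 300-kb contig of uniform base
#' composition, 30 ChIP peaks and 90 ATAC peaks of 600 bp, 24 planted H-H
#' pairs of the canonical inverted-repeat forkhead pattern at a 4-nt gap
#' inside ChIP peaks, 24 planted TnG arrays (half short at 20 bp, half
#' long at 48 bp; within each length class half abut a planted H-H site
#' in the aligned configuration and half lie over 1 kb from every H-H),
#' triangular coverage bumps over ChIP peaks plus repeat-centered bumps
#' whose height is boosted for H-H-adjacent repeats, and an 80-gene DE
#' table in which low-p genes are preferentially placed near planted
#' features.
#'
#' @param ... named overrides of any default listed above.
#' @return a configuration list.
#' @export
sim_genome_config <- function(...) {
  cfg <- list(
    chrom = "chr1",
    chrom_len = 300000L,
    gc = 0.5,
    n_chip_peaks = 30L,
    n_atac_peaks = 90L,
    peak_width = 600L,
    # planted pair sites: one row per batch
    planted_pairs = data.frame(
      motif_a = "TGTTTNN", motif_b = "TGTTTNN", orientation = "HH",
      gap_size = 4L, n = 24L, where = "chip",
      stringsAsFactors = FALSE
    ),
    # planted TnG arrays: unit repeated n_units times; hh_link is
    # "zero_gap" (abutting a planted H-H, aligned) or "far" (>1 kb away)
    planted_tng = data.frame(
      unit = "TTTG",
      n_units = rep(c(5L, 12L), each = 2L),
      strand = "+",
      n = 6L,
      hh_link = rep(c("zero_gap", "far"), times = 2L),
      stringsAsFactors = FALSE
    ),
    coverage_height = 10,
    tng_cov_height = 2,
    tng_cov_boost = 8,
    n_genes = 80L,
    gene_width = 2000L,
    gene_near_max = 500L,
    gene_far_min = 5000L,
    max_attempts = 200L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# instantiate a degenerate pattern by sampling each position uniformly
# from its base set
instantiate_pattern <- function(pattern) {
  ch <- strsplit(dna_normalize(pattern), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- vapply(ch, function(x) {
    allowed <- bases[bitwAnd(.IUPAC_BITS[bases], .IUPAC_BITS[[x]]) ==
                       .IUPAC_BITS[bases]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Simulate a genome bundle with planted features
#'
#' Generates an i.i.d. background contig, non-overlapping ChIP and ATAC
#' peak intervals, planted oriented pair sites (inside peaks), planted
#' TnG arrays in configured spatial relation to the planted H-H sites,
#' a piecewise-triangular coverage track, and a DE gene table whose
#' significance structure is linked to feature proximity.  All planted
#' features are returned as ground-truth interval tables.  Deterministic
#' under `seed`; identical seed and configuration give identical output.
#' Placement collisions are retried and raise an error after
#' `max_attempts` failures.
#'
#' @param seed integer seed.
#' @param config configuration list from [sim_genome_config()].
#' @return a list: `genome` (named character), `chip_peaks`, `atac_peaks`,
#'   `planted_hh`, `planted_tng` (interval `data.frame`s), `coverage`
#'   (bedGraph-style `data.frame`), `genes` (DE table) and `config`.
#' @export
sim_genome <- function(seed, config = sim_genome_config()) {
  set.seed(seed)
  cfg <- config
  L <- cfg$chrom_len
  base_probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  seq_chr <- strsplit(random_kmers(1L, L, base_probs), "", fixed = TRUE)[[1]]

  # non-overlapping peaks on a slot grid, chip and atac interleaved
  slot <- cfg$peak_width + 200L
  n_slots <- L %/% slot
  n_peaks <- cfg$n_chip_peaks + cfg$n_atac_peaks
  if (n_peaks > n_slots) stop("chromosome too short for requested peaks")
  picks <- sort(sample.int(n_slots, n_peaks))
  starts <- (picks - 1L) * slot + 100L
  is_chip <- seq_len(n_peaks) %in%
    sample.int(n_peaks, cfg$n_chip_peaks)
  chip <- intervals(cfg$chrom, starts[is_chip],
                    starts[is_chip] + cfg$peak_width)
  atac <- intervals(cfg$chrom, starts[!is_chip],
                    starts[!is_chip] + cfg$peak_width)

  occupied <- matrix(integer(0), ncol = 2L)  # planted footprints
  collides <- function(s, e) {
    nrow(occupied) && any(s < occupied[, 2L] & e > occupied[, 1L])
  }
  claim <- function(s, e) occupied <<- rbind(occupied, c(s, e))

  write_seq <- function(s, txt) {
    seq_chr[(s + 1L):(s + nchar(txt))] <<- strsplit(txt, "", fixed = TRUE)[[1]]
  }

  # ---- planted pair sites ----
  hh_rows <- list()
  pp <- cfg$planted_pairs
  for (r in seq_len(nrow(pp))) {
    target <- if (pp$where[r] == "chip") chip else atac
    plen <- 14L + pp$gap_size[r]
    pat <- render_pair(pp$motif_a[r], pp$motif_b[r], pp$orientation[r],
                       strrep("N", pp$gap_size[r]))
    for (k in seq_len(pp$n[r])) {
      placed <- FALSE
      for (att in seq_len(cfg$max_attempts)) {
        pk <- target[sample.int(nrow(target), 1L), ]
        s <- pk$start + sample.int(pk$end - pk$start - plen, 1L)
        # margin so abutting TnG arrays stay inside reach
        if (collides(s - 60L, s + plen + 60L)) next
        write_seq(s, instantiate_pattern(pat))
        claim(s - 60L, s + plen + 60L)
        hh_rows[[length(hh_rows) + 1L]] <- data.frame(
          chrom = cfg$chrom, start = s, end = s + plen, strand = "+",
          motif_a = pp$motif_a[r], motif_b = pp$motif_b[r],
          orientation = pp$orientation[r], gap_size = pp$gap_size[r],
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted pair site (max attempts)")
    }
  }
  planted_hh <- do.call(rbind, hh_rows)
  if (is.null(planted_hh)) {
    planted_hh <- data.frame(chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             motif_a = character(), motif_b = character(),
                             orientation = character(),
                             gap_size = integer(), stringsAsFactors = FALSE)
  }

  # ---- planted TnG arrays ----
  tng_rows <- list()
  pt <- cfg$planted_tng
  hh_pool <- if (nrow(planted_hh)) sample.int(nrow(planted_hh)) else integer(0)
  for (r in seq_len(nrow(pt))) {
    txt <- strrep(pt$unit[r], pt$n_units[r])
    if (pt$strand[r] == "-") txt <- revcomp(txt)
    tlen <- nchar(txt)
    for (k in seq_len(pt$n[r])) {
      placed <- FALSE
      for (att in seq_len(cfg$max_attempts)) {
        guard <- if (pt$strand[r] == "+") "C" else "G"
        if (pt$hh_link[r] == "zero_gap") {
          if (!length(hh_pool)) stop("no free H-H site to link a repeat to")
          hi <- hh_pool[1L]
          # aligned: + repeat abuts upstream, - (CAn) abuts downstream
          s <- if (pt$strand[r] == "+") {
            planted_hh$start[hi] - tlen
          } else {
            planted_hh$end[hi]
          }
          if (s < 1L || s + tlen + 1L > L) next
          hh_pool <- hh_pool[-1L]
        } else {
          s <- sample.int(L - tlen - 2L, 1L)
          near_hh <- nrow(planted_hh) > 0L &&
            any(pmax(planted_hh$start - (s + tlen), s - planted_hh$end) <
                  1200L)
          if (near_hh || collides(s - 10L, s + tlen + 10L)) next
        }
        # guard bases on background-facing ends keep the maximal detected
        # array identical to the planted interval
        write_seq(s, txt)
        if (!(pt$hh_link[r] == "zero_gap" && pt$strand[r] == "-")) {
          write_seq(s - 1L, guard)
        }
        if (!(pt$hh_link[r] == "zero_gap" && pt$strand[r] == "+")) {
          write_seq(s + tlen, guard)
        }
        claim(s - 1L, s + tlen + 1L)
        tng_rows[[length(tng_rows) + 1L]] <- data.frame(
          chrom = cfg$chrom, start = s, end = s + tlen,
          strand = pt$strand[r], repeat_length = tlen,
          hh_link = pt$hh_link[r], stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted TnG array (max attempts)")
    }
  }
  planted_tng <- do.call(rbind, tng_rows)
  if (is.null(planted_tng)) {
    planted_tng <- data.frame(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              repeat_length = integer(),
                              hh_link = character(), stringsAsFactors = FALSE)
  }

  genome <- stats::setNames(paste(seq_chr, collapse = ""), cfg$chrom)

  # ---- coverage: triangular bumps ----
  tri <- function(center, halfwidth, height) {
    pos <- (center - halfwidth):(center + halfwidth - 1L)
    keep <- pos >= 0L & pos < L
    pos <- pos[keep]
    data.frame(chrom = cfg$chrom, start = pos, end = pos + 1L,
               value = height * (1 - abs(pos + 0.5 - center) / halfwidth))
  }
  bumps <- list()
  for (i in seq_len(nrow(chip))) {
    bumps[[length(bumps) + 1L]] <-
      tri((chip$start[i] + chip$end[i]) %/% 2L, cfg$peak_width %/% 2L,
          cfg$coverage_height)
  }
  for (i in seq_len(nrow(planted_tng))) {
    h <- if (planted_tng$hh_link[i] == "zero_gap") {
      cfg$tng_cov_height * cfg$tng_cov_boost
    } else {
      cfg$tng_cov_height
    }
    bumps[[length(bumps) + 1L]] <-
      tri((planted_tng$start[i] + planted_tng$end[i]) %/% 2L, 100L, h)
  }
  coverage <- do.call(rbind, bumps)
  # collapse duplicate bases by summing
  key <- coverage$start
  agg <- rowsum(coverage$value, key)
  coverage <- data.frame(chrom = cfg$chrom,
                         start = as.integer(rownames(agg)),
                         end = as.integer(rownames(agg)) + 1L,
                         value = agg[, 1L])
  coverage <- coverage[order(coverage$start), , drop = FALSE]
  rownames(coverage) <- NULL

  # ---- DE gene table linked to feature proximity ----
  feats <- rbind(planted_hh[, c("chrom", "start", "end")],
                 planted_tng[, c("chrom", "start", "end")])
  n_genes <- cfg$n_genes
  padj <- pmin(1, 10 ^ stats::runif(n_genes, -12, 0.5))
  log2fc <- stats::rnorm(n_genes, 0, 2)
  near <- stats::runif(n_genes) < pmin(1, -log10(padj) / 10)
  gs <- integer(n_genes)
  gw <- cfg$gene_width
  for (i in seq_len(n_genes)) {
    for (att in seq_len(cfg$max_attempts)) {
      if (near[i] && nrow(feats)) {
        f <- feats[sample.int(nrow(feats), 1L), ]
        s <- f$start + sample.int(2L * cfg$gene_near_max, 1L) -
          cfg$gene_near_max - gw %/% 2L
        s <- max(0L, min(s, L - gw))
        ok <- TRUE
      } else {
        s <- sample.int(L - gw, 1L)
        ok <- nrow(feats) == 0L ||
          all(pmax(feats$start - (s + gw), s - feats$end) > cfg$gene_far_min)
      }
      if (ok) { gs[i] <- s; break }
      if (att == cfg$max_attempts) stop("could not place gene (max attempts)")
    }
  }
  genes <- data.frame(gene = paste0("gene", seq_len(n_genes)),
                      chrom = cfg$chrom, start = gs, end = gs + gw,
                      log2fc = log2fc, padj = padj,
                      stringsAsFactors = FALSE)

  list(genome = genome, chip_peaks = chip, atac_peaks = atac,
       planted_hh = planted_hh, planted_tng = planted_tng,
       coverage = coverage, genes = genes, config = cfg)
}

#' Write a simulated genome bundle to disk
#'
#' @param bundle result of [sim_genome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.  Writes `genome.fa`,
#'   `chip_peaks.bed`, `atac_peaks.bed`, `planted_hh.bed`,
#'   `planted_tng.bed`, `coverage.bedgraph`, `genes.tsv`.
#' @export
write_genome_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_bed(bundle$chip_peaks, file.path(dir, "chip_peaks.bed"))
  write_bed(bundle$atac_peaks, file.path(dir, "atac_peaks.bed"))
  if (nrow(bundle$planted_hh)) {
    write_bed(bundle$planted_hh, file.path(dir, "planted_hh.bed"))
  }
  if (nrow(bundle$planted_tng)) {
    write_bed(bundle$planted_tng, file.path(dir, "planted_tng.bed"))
  }
  write_bedgraph(bundle$coverage, file.path(dir, "coverage.bedgraph"))
  write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}
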