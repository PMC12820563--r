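# Gene association: relate features (H-H sites, TnG repeats) to a
# differential-expression table via feature-density profiles over
# expanding windows and fraction-of-genes-with-nearby-feature statistics
# binned by significance and fold-change direction.

# total feature bp overlapping [ws, we) per query row
overlap_bp <- function(chrom, ws, we, features) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    f <- features[features$chrom == ch, , drop = FALSE]
    if (!nrow(f)) next
    for (i in qi) {
      ov <- pmin(f$end, we[i]) - pmax(f$start, ws[i])
      out[i] <- sum(ov[ov > 0])
    }
  }
  out
}

#' Check / annotate a differential-expression gene table
#'
#' @param genes `data.frame` with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open gene body), `log2fc` and `padj`.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return the table with a logical `significant` column.
#' @export
de_gene_table <- function(genes, alpha = 0.05) {
  need <- c("gene", "chrom", "start", "end", "log2fc", "padj")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(genes$padj < 0 | genes$padj > 1, na.rm = TRUE)) {
    stop("padj must lie in [0, 1]")
  }
  genes$significant <- genes$padj < alpha
  genes
}

#' Feature-density profile over expanding windows
#'
#' For each gene and each window size `w`, expands the gene body by `w` bp
#' on both sides and measures the feature density (total feature bp
#' overlapping the window, per Mb of window length), then averages within
#' the significant (adjusted p below `alpha`) and non-significant gene
#' groups.
#'
#' @param genes a DE gene table (see [de_gene_table()]).
#' @param features interval `data.frame` of features.
#' @param windows ascending window sizes in bp (default 1 kb to 1 Mb).
#' @param alpha significance threshold (default 0.05).
#' @return `data.frame` with `window`, `group`
#'   (`significant`/`non_significant`), `n_genes`, `mean_density`
#'   (bp per Mb).
#' @export
density_profile <- function(genes, features,
                            windows = c(1e3, 1e4, 1e5, 1e6),
                            alpha = 0.05) {
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  genes <- de_gene_table(genes, alpha)
  out <- vector("list", length(windows))
  for (k in seq_along(windows)) {
    w <- as.integer(windows[k])
    ws <- pmax(genes$start - w, 0L)
    we <- genes$end + w
    dens <- overlap_bp(genes$chrom, ws, we, features) * 1e6 / (we - ws)
    out[[k]] <- data.frame(
      window = w,
      group = c("significant", "non_significant"),
      n_genes = c(sum(genes$significant), sum(!genes$significant)),
      mean_density = c(mean(dens[genes$significant]),
                       mean(dens[!genes$significant]))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of genes with a nearby feature, by significance bin
#'
#' Expands each gene body by `radius` bp on both sides and asks whether
#' the expansion overlaps at least one feature (half-open overlap;
#' abutment does not count).  Genes are binned by adjusted p-value and
#' split by log2 fold-change direction; the fraction of genes with a
#' nearby feature is reported per bin and direction.  Empty bins are
#' reported as `NA`.
#'
#' @param genes a DE gene table.
#' @param features interval `data.frame` of features.
#' @param radius expansion radius in bp (default 2000).
#' @param p_bins ascending break points partitioning \[0, 1\]
#'   (default `c(0, 1e-10, 1e-5, 0.05, 1)`).
#' @return `data.frame` with `p_bin`, `direction` (`up`/`down`),
#'   `n_genes`, `fraction`.
#' @export
fraction_within <- function(genes, features, radius = 2000L,
                            p_bins = c(0, 1e-10, 1e-5, 0.05, 1)) {
  genes <- de_gene_table(genes)
  ws <- pmax(genes$start - as.integer(radius), 0L)
  we <- genes$end + as.integer(radius)
  has <- overlap_bp(genes$chrom, ws, we, features) > 0
  bin <- cut(genes$padj, breaks = p_bins, include.lowest = TRUE,
             right = FALSE)
  # right-closed top bin so padj = 1 is kept
  bin[is.na(bin) & genes$padj == 1] <- levels(bin)[length(levels(bin))]
  direction <- ifelse(genes$log2fc >= 0, "up", "down")
  grid <- expand.grid(p_bin = levels(bin), direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  grid$n_genes <- NA_integer_
  grid$fraction <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- !is.na(bin) & bin == grid$p_bin[i] & direction == grid$direction[i]
    grid$n_genes[i] <- sum(sel)
    grid$fraction[i] <- if (any(sel)) mean(has[sel]) else NA_real_
  }
  grid
}
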