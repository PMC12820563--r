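# File I/O: BED / bedGraph through rtracklayer, FASTA / FASTQ through
# Biostrings.  Everything is converted to the package's plain-data
# representations (0-based half-open interval data.frames, named character
# vectors of sequence) at the boundary.

granges_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

intervals_to_granges <- function(x) {
  strand <- x$strand
  strand[is.null(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Read a BED file (3-6 columns)
#'
#' @param path path to a BED file.
#' @return interval `data.frame` (0-based half-open) with any name/score
#'   columns preserved.
#' @export
read_bed <- function(path) {
  granges_to_intervals(rtracklayer::import(path, format = "BED"))
}

#' Write intervals as BED6
#'
#' @param x interval `data.frame`; optional `name` and `score` columns are
#'   carried into the BED name/score fields.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  gr <- intervals_to_granges(x)
  if (!is.null(x$name)) S4Vectors::mcols(gr)$name <- x$name
  S4Vectors::mcols(gr)$score <- if (is.null(x$score)) 0 else x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased (soft-masked lowercase is accepted).
#'
#' @param path FASTA path.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ (or FASTA) file of reads
#'
#' @param path FASTQ/FASTA path (gz accepted).
#' @param format `"fastq"` or `"fasta"`.
#' @return a list with character vectors `seq` and `qual` (`qual` is `NULL`
#'   for FASTA input, in which case downstream quality filters are skipped
#'   with a warning).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    return(list(seq = toupper(as.character(ss)), qual = NULL))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  list(seq = toupper(as.character(ss)),
       qual = stats::setNames(as.character(S4Vectors::mcols(ss)$qualities),
                              names(ss)))
}

#' Write reads as FASTQ
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param qual quality strings (Sanger, offset 33); default constant Q30.
#' @param ids read identifiers.
#' @export
write_fastq <- function(seqs, path, qual = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  if (is.null(qual)) {
    qual <- vapply(nchar(seqs), function(w) strrep("?", w), character(1))
  }
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(qual)
  )
  names(ss) <- ids
  Biostrings::writeQualityScaledXStringSet(ss, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph path.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and `value`.
#' @export
read_bedgraph <- function(path) {
  df <- granges_to_intervals(rtracklayer::import(path, format = "bedGraph"))
  names(df)[names(df) == "score"] <- "value"
  df[, c("chrom", "start", "end", "value")]
}

#' Write a bedGraph coverage track
#'
#' @param x `data.frame` with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    score = x$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the conventions used by the pipeline's outputs
#' (header, no quoting, no row names).
#'
#' @param x a `data.frame`.
#' @param path file path.
#' @return `read_tsv` returns a `data.frame`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
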