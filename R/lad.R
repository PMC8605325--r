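#' Build a normalized genomic interval set
#'
#' Intervals are taken in BED convention (0-based half-open) and stored as a
#' `GRanges`; overlapping and adjacent intervals are merged and the result is
#' sorted. `GRanges` input is normalized in place.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), or a `GRanges`.
#' @return A sorted, reduced, unstranded `GRanges`.
#' @examples
#' genomic_interval_set(data.frame(chrom = "chrT", start = c(0, 50),
#'                                 end = c(100, 150)))
#' @export
genomic_interval_set <- function(x) {
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else {
    x <- as.data.frame(x)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (nrow(x) == 0L) return(GenomicRanges::GRanges())
    if (any(x$start < 0)) stop("negative coordinate")
    if (any(x$start >= x$end)) stop("interval with start >= end")
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
  }
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' @rdname genomic_interval_set
#' @export
normalize_intervals <- genomic_interval_set

#' Subtract one interval set from another
#'
#' Per-chromosome set difference `a \ b` in base pairs; the result is
#' normalized. Total lengths satisfy
#' `length(result) == length(a) - length(intersect(a, b))`.
#'
#' @param a,b Interval sets (anything accepted by [genomic_interval_set()]).
#' @return A normalized `GRanges`.
#' @export
subtract_intervals <- function(a, b) {
  a <- genomic_interval_set(a); b <- genomic_interval_set(b)
  if (length(b) == 0L) return(a)
  if (length(a) == 0L) return(a)
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomicRanges::reduce(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Total interval length in base pairs
#'
#' @param x Interval set; optionally restricted to one chromosome.
#' @param chrom Optional chromosome name.
#' @return Total covered length (bp).
#' @export
interval_total_length <- function(x, chrom = NULL) {
  gr <- genomic_interval_set(x)
  if (!is.null(chrom))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  sum(as.numeric(GenomicRanges::width(gr)))
}

#' Read a BED file of intervals
#'
#' Minimal three-column BED reader (0-based half-open); the result is
#' normalized.
#'
#' @param path BED file.
#' @return A normalized `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (length(readLines(path, n = 1L)) == 0L) return(GenomicRanges::GRanges())
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  genomic_interval_set(df)
}

#' Write intervals as a BED file
#'
#' @param x Interval set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- genomic_interval_set(x)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-lengths TSV
#'
#' @param path TSV with columns chromosome name and length (bp); no header.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' LAD percentage per chromosome
#'
#' Blacklist regions are subtracted from both the LAD intervals and the
#' chromosome lengths before the ratio is taken:
#' `100 * length(LAD \ blacklist) / (chrom_length - length(blacklist))`.
#' Chromosomes present in `lengths` but absent from the LAD input report 0.
#'
#' @param lads,blacklist Interval sets (the blacklist may be empty).
#' @param lengths Named numeric vector of chromosome lengths in bp (as from
#'   [read_chrom_lengths()]).
#' @return data.frame with columns `chromosome`, `lad_bp`,
#'   `effective_length_bp`, `lad_percent`.
#' @examples
#' lads <- genomic_interval_set(data.frame(chrom = "chrT", start = 0, end = 300))
#' bl <- genomic_interval_set(data.frame(chrom = "chrT", start = 0, end = 100))
#' lad_percent(lads, bl, c(chrT = 1000))  # 27.78%
#' @export
lad_percent <- function(lads, blacklist, lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0), !is.null(names(lengths)))
  lads <- genomic_interval_set(lads)
  blacklist <- if (missing(blacklist) || is.null(blacklist))
    GenomicRanges::GRanges() else genomic_interval_set(blacklist)
  lad_eff <- subtract_intervals(lads, blacklist)
  out <- lapply(names(lengths), function(chr) {
    bl_bp <- interval_total_length(blacklist, chr)
    eff_len <- lengths[[chr]] - bl_bp
    if (eff_len <= 0)
      stop(sprintf("blacklist covers all of chromosome %s", chr))
    lad_bp <- interval_total_length(lad_eff, chr)
    data.frame(chromosome = chr, lad_bp = lad_bp,
               effective_length_bp = eff_len,
               lad_percent = 100 * lad_bp / eff_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
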