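#' Genomic interval tables
#'
#' Throughout the package a set of genomic intervals is a plain
#' \code{data.frame} with columns \code{chrom} (character), \code{start}
#' (0-based inclusive), \code{end} (exclusive) and optionally \code{strand}
#' (\code{"+"}, \code{"-"} or \code{"*"}). All coordinates are 0-based
#' half-open; BED-family files are read verbatim, VCF positions are shifted
#' on read/write. \code{genomic_intervals()} builds and validates such a
#' table.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-like vectors, \code{0 <= start < end}.
#' @param strand optional strand vector; defaults to \code{"*"}.
#' @return a validated \code{data.frame} of intervals.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  n <- length(chrom)
  if (is.null(strand)) strand <- rep("*", n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval with empty chromosome name")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid interval (need 0 <= start < end) at row %d: [%s, %s)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  invisible(df)
}

#' @rdname genomic_intervals
#' @param x chromosome name vector.
#' @param strip_chr drop an optional \code{"chr"} prefix before comparison
#'   (default \code{TRUE}); mixed GRCh38 naming dialects are common.
#' @export
norm_chrom <- function(x, strip_chr = TRUE) {
  if (strip_chr) sub("^chr", "", as.character(x)) else as.character(x)
}

## internal: intervals data.frame -> GRanges (IRanges is 1-based closed)
as_granges <- function(df, strip_chr = TRUE) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom, strip_chr),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Find all overlapping interval pairs between two sets
#'
#' Reports every pair with the same chromosome and an intersection of at
#' least 1 bp, i.e. both partial overlaps and complete containment count.
#' The engine is \code{GenomicRanges::findOverlaps}; coordinates are
#' converted from the package's 0-based half-open convention.
#'
#' @param a,b interval \code{data.frame}s (see [genomic_intervals()]).
#' @param strip_chr normalize an optional \code{"chr"} prefix before
#'   matching chromosome names (default \code{TRUE}).
#' @return \code{data.frame} with columns \code{index_a}, \code{index_b},
#'   \code{overlap_length}, sorted by (\code{index_a}, \code{index_b}).
#' @examples
#' a <- genomic_intervals("chr1", 0, 100)
#' b <- genomic_intervals(c("chr1", "chr1"), c(50, 200), c(150, 300))
#' find_overlaps(a, b)
#' @export
find_overlaps <- function(a, b, strip_chr = TRUE) {
  validate_intervals(a); validate_intervals(b)
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      overlap_length = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  ## the two sets rarely share identical seqlevels; the engine warns on
  ## the mismatch, which is expected here
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a, strip_chr),
                                as_granges(b, strip_chr),
                                minoverlap = 1L))
  if (length(hits) == 0L) return(empty)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  len <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  o <- order(ia, ib)
  data.frame(index_a = ia[o], index_b = ib[o], overlap_length = len[o])
}

#' Gap between two genomic intervals
#'
#' Distance in bp between the nearest edges of two intervals on the same
#' chromosome; 0 if they overlap or abut. Intervals on different
#' chromosomes have no defined gap and return \code{NA}.
#'
#' @param a,b single-row interval \code{data.frame}s.
#' @param strip_chr see [find_overlaps()].
#' @return non-negative number of bp, or \code{NA} for different
#'   chromosomes.
#' @export
interval_gap <- function(a, b, strip_chr = TRUE) {
  validate_intervals(a); validate_intervals(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (norm_chrom(a$chrom, strip_chr) != norm_chrom(b$chrom, strip_chr))
    return(NA_real_)
  max(0, a$start - b$end, b$start - a$end)
}
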