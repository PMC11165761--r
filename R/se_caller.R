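#' Stitch enhancer peaks into candidate regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap is at most
#' \code{stitch_distance} are merged transitively into one region whose
#' span runs from the minimum start to the maximum end of its
#' constituents and whose score is the sum of constituent signals.
#' Optionally, peaks fully contained within \code{tss_exclusion} bp of any
#' transcription start site are removed before stitching, to keep
#' promoter-proximal acetylation out of the enhancer ranking.
#'
#' @param peaks peak \code{data.frame} from one sample (see
#'   [read_peaks()]).
#' @param stitch_distance maximum gap in bp merged across (default
#'   12500, the ROSE convention); a gap exactly equal to the distance is
#'   merged.
#' @param tss_exclusion half-width in bp of the promoter exclusion zone
#'   (default 0 = off). Requires \code{gene_models}.
#' @param gene_models gene-model table (see [read_gene_models()]),
#'   needed only when \code{tss_exclusion > 0}.
#' @return \code{data.frame} with \code{chrom, start, end,
#'   constituent_count, total_signal, sample_id}, sorted by (chrom,
#'   start, end).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss_exclusion = 0,
                         gene_models = NULL) {
  stopifnot(stitch_distance >= 0)
  if (tss_exclusion > 0 && is.null(gene_models))
    stop("tss_exclusion > 0 requires gene_models")
  sample_id <- if (nrow(peaks)) peaks$sample_id[1] else character()
  if (tss_exclusion > 0 && nrow(peaks)) {
    drop <- rep(FALSE, nrow(peaks))
    for (g in seq_len(nrow(gene_models))) {
      same <- norm_chrom(peaks$chrom) == norm_chrom(gene_models$chrom[g])
      drop <- drop | (same &
        peaks$start >= gene_models$tss[g] - tss_exclusion &
        peaks$end <= gene_models$tss[g] + tss_exclusion)
    }
    peaks <- peaks[!drop, , drop = FALSE]
  }
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      constituent_count = integer(), total_signal = numeric(),
                      sample_id = character()))
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  out <- list()
  for (chr in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    ## running maximum of ends so contained peaks do not reset the gap
    hi <- cummax(p$end)
    gap <- p$start[-1] - hi[-nrow(p)]
    grp <- cumsum(c(1, as.integer(gap > stitch_distance)))
    out[[chr]] <- data.frame(
      chrom = chr,
      start = tapply(p$start, grp, min),
      end = tapply(p$end, grp, max),
      constituent_count = as.integer(tapply(p$start, grp, length)),
      total_signal = as.numeric(tapply(p$signal, grp, sum)),
      sample_id = sample_id, row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Rank stitched regions and cut super-enhancers from typical enhancers
#'
#' Rank ordering of super-enhancers: regions are sorted by total signal
#' ascending, rank index and signal are each rescaled to \[0, 1\], and the
#' cutoff is the point where a 45-degree line first touches the scaled
#' rank-signal curve when raised from below (the geometric tangent of
#' slope 1; on a convex hockey stick this is where the curve's slope,
#' scanning from the high-signal end, drops to 1). Regions with total
#' signal strictly above the cutoff signal are super-enhancers. When all
#' signals are equal the curve is flat and no region is called super.
#'
#' @param regions stitched-region \code{data.frame} from
#'   [stitch_peaks()].
#' @return list with \code{cutoff_signal} and \code{calls}, the input
#'   with added \code{rank} (1 = highest signal), \code{is_super} and
#'   \code{cutoff_signal} columns, sorted by rank.
#' @export
rank_and_cut <- function(regions) {
  n <- nrow(regions)
  if (n == 0L) stop("rank_and_cut: no regions")
  s <- sort(regions$total_signal)
  if (n == 1L || s[n] == s[1]) {
    cutoff <- s[n]                     # flat curve: nothing is super
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    ## the slope-1 support line y = x + c touches the curve where y - x
    ## is minimal; that contact point is the cutoff
    cutoff <- s[which.min(y - x)]
  }
  ord <- order(-regions$total_signal, regions$chrom, regions$start, regions$end)
  calls <- regions[ord, , drop = FALSE]
  calls$rank <- seq_len(n)
  calls$is_super <- calls$total_signal > cutoff
  calls$cutoff_signal <- cutoff
  rownames(calls) <- NULL
  list(cutoff_signal = cutoff, calls = calls)
}

#' Call super-enhancers from one sample's peaks
#'
#' Composition of [stitch_peaks()] and [rank_and_cut()]. An empty peak
#' list yields an empty call table (no cutoff is defined).
#'
#' @inheritParams stitch_peaks
#' @param out optional path; when given, calls are also written as BED
#'   with columns chrom, start, end, region_id, total_signal, rank,
#'   is_super.
#' @return SE call \code{data.frame} (see [rank_and_cut()]) with an added
#'   \code{region_id} column.
#' @export
call_super_enhancers <- function(peaks, stitch_distance = 12500,
                                 tss_exclusion = 0, gene_models = NULL,
                                 out = NULL) {
  regions <- stitch_peaks(peaks, stitch_distance, tss_exclusion, gene_models)
  if (nrow(regions) == 0L) {
    calls <- cbind(regions, rank = integer(), is_super = logical(),
                   cutoff_signal = numeric())
  } else {
    calls <- rank_and_cut(regions)$calls
  }
  calls$region_id <- if (nrow(calls))
    sprintf("%s_SE%04d", calls$sample_id, calls$rank) else character()
  if (!is.null(out))
    write_bed(calls, out, c("region_id", "total_signal", "rank", "is_super"))
  calls
}
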