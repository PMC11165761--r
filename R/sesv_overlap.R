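#' Intersect super-enhancer calls with SV breakpoint windows
#'
#' One record per intersecting (SE region, breakpoint window) pair, with
#' at least 1 bp of intersection required. When several windows of the
#' same SV hit the same SE region (e.g. both breakends of a small
#' deletion), only the record with the largest overlap is kept, so one SV
#' contributes at most one record per SE region.
#'
#' @param se_calls SE call \code{data.frame} (see
#'   [call_super_enhancers()]); only rows with \code{is_super} are used
#'   unless \code{super_only = FALSE}.
#' @param windows breakpoint window \code{data.frame} (see
#'   [make_windows()]) from the same sample. Multi-sample tables are
#'   accepted: rows are paired only within matching \code{sample_id},
#'   so a whole cohort can be intersected in one call.
#' @param super_only restrict to super-enhancer regions (default
#'   \code{TRUE}); set \code{FALSE} to include typical enhancers for
#'   sensitivity analysis.
#' @return \code{data.frame} with \code{sample_id, se_chrom, se_start,
#'   se_end, sv_id, breakpoint_pos, overlap_length}.
#' @export
overlap_se_sv <- function(se_calls, windows, super_only = TRUE) {
  if (super_only && nrow(se_calls))
    se_calls <- se_calls[se_calls$is_super, , drop = FALSE]
  empty <- data.frame(sample_id = character(), se_chrom = character(),
                      se_start = numeric(), se_end = numeric(),
                      sv_id = character(), breakpoint_pos = numeric(),
                      overlap_length = numeric())
  if (nrow(se_calls) == 0L || nrow(windows) == 0L) return(empty)
  ## composite sample|chrom key restricts pairing to within-sample
  se_k <- se_calls
  se_k$chrom <- paste(se_calls$sample_id, norm_chrom(se_calls$chrom), sep = "|")
  win_k <- windows
  win_k$chrom <- paste(windows$sample_id, norm_chrom(windows$chrom), sep = "|")
  hits <- find_overlaps(se_k, win_k, strip_chr = FALSE)
  if (nrow(hits) == 0L) return(empty)
  res <- data.frame(sample_id = se_calls$sample_id[hits$index_a],
                    se_chrom = se_calls$chrom[hits$index_a],
                    se_start = se_calls$start[hits$index_a],
                    se_end = se_calls$end[hits$index_a],
                    sv_id = windows$sv_id[hits$index_b],
                    breakpoint_pos = windows$breakpoint_pos[hits$index_b],
                    overlap_length = hits$overlap_length,
                    stringsAsFactors = FALSE)
  ## dedup: max-overlap record per (sample, SE region, SV)
  key <- paste(res$sample_id, res$se_chrom, res$se_start, res$se_end,
               res$sv_id, sep = "\r")
  ord <- order(key, -res$overlap_length, res$breakpoint_pos)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(key[ord]), , drop = FALSE]
  res <- res[order(res$sample_id, res$se_chrom, res$se_start, res$se_end,
                   res$sv_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-sample SV and SE-SV overlap frequencies
#'
#' Counts per sample the consolidated SV calls and the distinct
#' (SE region, SV) overlap pairs, and log2-transforms both as
#' \code{log2(count + 1)} so samples with zero events stay defined.
#'
#' @param records overlap records from [overlap_se_sv()], concatenated
#'   across samples.
#' @param sv_calls consolidated SV calls, concatenated across samples.
#' @param samples clinical \code{data.frame} with \code{sample_id} and
#'   \code{cohort} (every cohort sample appears in the summary; samples
#'   without SV data get count 0 with a note).
#' @return \code{data.frame} with \code{sample_id, cohort, n_sv,
#'   n_overlap, log2_sv, log2_overlap}.
#' @export
per_sample_frequency <- function(records, sv_calls, samples) {
  n_sv <- table(factor(sv_calls$sample_id, levels = samples$sample_id))
  n_ov <- table(factor(records$sample_id, levels = samples$sample_id))
  missing <- setdiff(samples$sample_id, unique(sv_calls$sample_id))
  if (length(missing))
    message(sprintf("note: %d sample(s) without SV calls counted as 0: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  data.frame(sample_id = samples$sample_id, cohort = samples$cohort,
             n_sv = as.integer(n_sv), n_overlap = as.integer(n_ov),
             log2_sv = log2(as.integer(n_sv) + 1),
             log2_overlap = log2(as.integer(n_ov) + 1),
             stringsAsFactors = FALSE)
}

#' Compare per-sample frequencies between cohorts
#'
#' Student's two-sample equal-variance two-sided t-test on the
#' log2-transformed counts, run separately for SV frequency and SE-SV
#' overlap frequency. The statistic is oriented non-CAGA minus CAGA.
#'
#' @param summary output of [per_sample_frequency()].
#' @return \code{data.frame} with one row per metric: \code{metric,
#'   t_statistic, p_value, mean_noncaga, mean_caga}.
#' @export
compare_cohort_frequencies <- function(summary) {
  g <- split(seq_len(nrow(summary)), summary$cohort)
  if (!all(c("CAGA", "non-CAGA") %in% names(g)))
    stop("both cohorts (CAGA, non-CAGA) are required")
  if (any(lengths(g) < 2L)) stop("each cohort needs at least 2 samples")
  one <- function(col) {
    tt <- stats::t.test(summary[[col]][g[["non-CAGA"]]],
                        summary[[col]][g[["CAGA"]]],
                        var.equal = TRUE)
    data.frame(metric = col, t_statistic = unname(tt$statistic),
               p_value = tt$p.value,
               mean_noncaga = unname(tt$estimate[1]),
               mean_caga = unname(tt$estimate[2]),
               stringsAsFactors = FALSE)
  }
  rbind(one("log2_sv"), one("log2_overlap"))
}

#' Assign genes to overlapped SE regions
#'
#' A gene is assigned to an SE region when its TSS lies within the region
#' extended by \code{flank} bp on both sides (half-open: a TSS exactly at
#' \code{end + flank} is outside).
#'
#' @param records overlap records from [overlap_se_sv()].
#' @param gene_models gene-model table (see [read_gene_models()]).
#' @param flank extension in bp (default 50000).
#' @return \code{data.frame} with \code{se_chrom, se_start, se_end,
#'   gene_id, symbol}, one row per (region, gene) assignment over the
#'   distinct SE regions in \code{records}.
#' @export
annotate_overlap_genes <- function(records, gene_models, flank = 50000) {
  empty <- data.frame(se_chrom = character(), se_start = numeric(),
                      se_end = numeric(), gene_id = character(),
                      symbol = character())
  if (nrow(records) == 0L) return(empty)
  reg <- unique(records[, c("se_chrom", "se_start", "se_end")])
  out <- list()
  for (i in seq_len(nrow(reg))) {
    same <- norm_chrom(gene_models$chrom) == norm_chrom(reg$se_chrom[i])
    hit <- same & gene_models$tss >= reg$se_start[i] - flank &
      gene_models$tss < reg$se_end[i] + flank
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        se_chrom = reg$se_chrom[i], se_start = reg$se_start[i],
        se_end = reg$se_end[i], gene_id = gene_models$gene_id[hit],
        symbol = gene_models$symbol[hit], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$se_chrom, res$se_start, res$se_end, res$gene_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
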