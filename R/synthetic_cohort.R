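#' Default synthetic-cohort configuration
#'
#' The defaults emulate, at desk scale, the study conditions of a
#' two-cohort lung-adenocarcinoma design: a larger cohort without
#' clinically actionable alterations (non-CAGA) and a smaller CAGA
#' cohort; hundreds of H3K27Ac peaks per sample with a heavy-tailed
#' (log-normal) signal distribution so that rank ordering yields a
#' hockey-stick curve; tens of SVs per sample; a set of planted genes
#' whose carrier samples receive a high-signal stitched peak cluster
#' near the TSS, an SV breakpoint inside that cluster, and upper-tail
#' outlier expression; and exponential recurrence-free survival with an
#' elevated hazard for truly outlier-positive cases.
#'
#' @param n_noncaga,n_caga samples per cohort (default 120 / 40).
#' @param genome named numeric vector of chromosome lengths in bp
#'   (default 3 chromosomes of 60 Mb).
#' @param n_genes number of gene models (default 200).
#' @param peaks_per_sample consensus background peak count (default
#'   300).
#' @param sv_per_sample mean background SV count per sample, Poisson
#'   (default 30).
#' @param n_planted planted SE-SV-driven genes (default 20); must not
#'   exceed \code{n_genes}.
#' @param planted_effect expression shift for carriers in SD units
#'   (default 3).
#' @param planted_rate fraction of cohort samples carrying each planted
#'   event (default 0.05, i.e. 8 carriers at the default size: any one
#'   driven gene is rare).
#' @param positive_rate fraction of non-CAGA samples eligible to carry
#'   planted events (default 0.4, the pool from which every gene's
#'   carriers are drawn, so roughly 40 percent of non-CAGA cases end up
#'   outlier-positive while each gene stays rare).
#' @param noise_sd baseline expression noise SD on the log scale
#'   (default 1).
#' @param baseline_hazard exponential event rate per month (default
#'   0.02).
#' @param hazard_ratio hazard multiplier for outlier-positive cases
#'   (default 3).
#' @param censor_range administrative censoring window in months,
#'   uniform (default c(12, 60)).
#' @param seed master seed; named sub-streams are derived from it so
#'   stages can be regenerated independently.
#' @return a \code{list} config for [generate_cohort()].
#' @export
synthetic_config <- function(n_noncaga = 120, n_caga = 40,
                             genome = c(chr1 = 6e7, chr2 = 6e7, chr3 = 6e7),
                             n_genes = 200, peaks_per_sample = 300,
                             sv_per_sample = 30, n_planted = 20,
                             planted_effect = 3, planted_rate = 0.05,
                             positive_rate = 0.4,
                             noise_sd = 1, baseline_hazard = 0.02,
                             hazard_ratio = 3, censor_range = c(12, 60),
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_noncaga > 0, n_caga > 0, n_genes > 0, peaks_per_sample > 0,
            sv_per_sample > 0, planted_rate >= 0, planted_rate <= 1,
            positive_rate > 0, positive_rate <= 1,
            hazard_ratio > 0, noise_sd > 0, all(genome > 0))
  if (n_planted > n_genes)
    stop("synthetic_config: n_planted exceeds n_genes")
  cfg
}

## deterministic sub-seed per named stream, kept below 2^31
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 1009 + h) %% 2147483647
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Produces per-sample peak tables, per-sample SV calls, a consensus
#' peak-signal matrix, an expression matrix, gene models, a clinical
#' table and the planted ground truth, all in memory. The same config
#' (including seed) always yields identical output.
#'
#' Planted events: each planted gene gets a cluster of 3-8 peaks within
#' 30 kb of its TSS (gaps well under the stitch distance); in carrier
#' samples the cluster peaks carry 10x log-normal signal and one SV has
#' a breakpoint placed inside the cluster span, so the 20 kb breakpoint
#' window is guaranteed to intersect the called super-enhancer. Carrier
#' expression is shifted by \code{planted_effect} SD and raised, if
#' needed, above the non-carriers' Q3 + 2 IQR; non-carrier values for
#' planted genes are winsorized at their own Q3 + 1.5 IQR so they can
#' never be flagged.
#'
#' @param config list from [synthetic_config()].
#' @return list with \code{peaks} (named list of per-sample peak
#'   \code{data.frame}s), \code{sv} (named list of per-sample SV call
#'   \code{data.frame}s), \code{peak_signal} (peaks x samples matrix),
#'   \code{consensus_peaks}, \code{expression} (genes x samples, rownames
#'   are gene ids), \code{gene_models}, \code{clinical}, \code{truth}
#'   (list: \code{planted_genes}, \code{carriers} data.frame,
#'   \code{positive} logical vector), and \code{config}.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cfg <- config
  samples <- c(sprintf("NC%03d", seq_len(cfg$n_noncaga)),
               sprintf("CA%03d", seq_len(cfg$n_caga)))
  cohort <- rep(c("non-CAGA", "CAGA"), c(cfg$n_noncaga, cfg$n_caga))
  chroms <- names(cfg$genome)

  ## --- gene models ---------------------------------------------------
  set.seed(sub_seed(cfg$seed, "genes"))
  g_chr <- sample(chroms, cfg$n_genes, replace = TRUE,
                  prob = cfg$genome / sum(cfg$genome))
  g_start <- floor(stats::runif(cfg$n_genes, 1e6, cfg$genome[g_chr] - 1e6))
  g_len <- floor(stats::runif(cfg$n_genes, 5e3, 5e4))
  g_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_models <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    symbol = sprintf("GENE%04d", seq_len(cfg$n_genes)),
    chrom = g_chr, start = g_start, end = g_start + g_len,
    strand = g_strand, stringsAsFactors = FALSE)
  gene_models$tss <- ifelse(g_strand == "-", gene_models$end - 1,
                            gene_models$start)
  planted <- sort(sample(cfg$n_genes, cfg$n_planted))
  planted_ids <- gene_models$gene_id[planted]

  ## --- consensus peaks (background + planted clusters) ---------------
  set.seed(sub_seed(cfg$seed, "peaks"))
  p_chr <- sample(chroms, cfg$peaks_per_sample, replace = TRUE,
                  prob = cfg$genome / sum(cfg$genome))
  p_start <- floor(stats::runif(cfg$peaks_per_sample, 0,
                                cfg$genome[p_chr] - 2e3))
  p_w <- floor(stats::runif(cfg$peaks_per_sample, 500, 2000))
  bg <- data.frame(chrom = p_chr, start = p_start, end = p_start + p_w,
                   planted_gene = NA_character_, stringsAsFactors = FALSE)
  cl <- list()
  for (gi in planted) {
    m <- sample(3:8, 1)
    tss <- gene_models$tss[gi]
    anchor <- max(0, tss - 15000)
    starts <- anchor + cumsum(c(0, stats::runif(m - 1, 2000, 6000)))
    w <- floor(stats::runif(m, 800, 2000))
    cl[[length(cl) + 1L]] <- data.frame(
      chrom = gene_models$chrom[gi], start = floor(starts),
      end = floor(starts) + w, planted_gene = gene_models$gene_id[gi],
      stringsAsFactors = FALSE)
  }
  consensus <- rbind(bg, do.call(rbind, cl))
  consensus <- consensus[order(consensus$chrom, consensus$start, consensus$end), ,
                         drop = FALSE]
  consensus$name <- sprintf("peak_%05d", seq_len(nrow(consensus)))
  rownames(consensus) <- NULL

  ## --- carriers: per-gene carriers drawn from a positive pool ---------
  set.seed(sub_seed(cfg$seed, "carriers"))
  n_car <- max(2L, round(cfg$planted_rate * length(samples)))
  pool <- sample(samples[cohort == "non-CAGA"],
                 max(n_car, round(cfg$positive_rate * cfg$n_noncaga)))
  carriers <- if (length(planted_ids))
    do.call(rbind, lapply(planted_ids, function(g)
      data.frame(gene_id = g, sample_id = sample(pool, n_car),
                 stringsAsFactors = FALSE)))
  else data.frame(gene_id = character(), sample_id = character(),
                  stringsAsFactors = FALSE)

  ## --- per-sample peak signal -----------------------------------------
  set.seed(sub_seed(cfg$seed, "signal"))
  np <- nrow(consensus)
  sig <- matrix(stats::rlnorm(np * length(samples)), np, length(samples),
                dimnames = list(consensus$name, samples))
  for (g in planted_ids) {
    rows <- which(consensus$planted_gene %in% g)
    cars <- carriers$sample_id[carriers$gene_id == g]
    sig[rows, cars] <- sig[rows, cars] * 10
  }
  peaks <- lapply(samples, function(s) {
    df <- data.frame(chrom = consensus$chrom, start = consensus$start,
                     end = consensus$end, name = consensus$name,
                     signal = sig[, s], sample_id = s,
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
  names(peaks) <- samples

  ## --- SV calls ---------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "svs"))
  sv <- lapply(samples, function(s) {
    k <- stats::rpois(1, cfg$sv_per_sample)
    recs <- list()
    if (k > 0) {
      type <- sample(sv_types, k, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
      for (i in seq_len(k)) {
        c1 <- sample(chroms, 1)
        if (type[i] == "TRA") {
          c2 <- sample(setdiff(chroms, c1), 1)
          recs[[i]] <- data.frame(sv_id = sprintf("%s_bg%03d", s, i),
                                  sample_id = s, sv_type = "TRA", chrom1 = c1,
                                  pos1 = floor(stats::runif(1, 1e4, cfg$genome[c1] - 1e4)),
                                  chrom2 = c2,
                                  pos2 = floor(stats::runif(1, 1e4, cfg$genome[c2] - 1e4)),
                                  quality = round(stats::runif(1, 20, 60)),
                                  support = 1L, stringsAsFactors = FALSE)
        } else if (type[i] == "INS") {
          recs[[i]] <- data.frame(sv_id = sprintf("%s_bg%03d", s, i),
                                  sample_id = s, sv_type = "INS", chrom1 = c1,
                                  pos1 = floor(stats::runif(1, 1e4, cfg$genome[c1] - 1e4)),
                                  chrom2 = NA_character_, pos2 = NA_real_,
                                  quality = round(stats::runif(1, 20, 60)),
                                  support = 1L, stringsAsFactors = FALSE)
        } else {
          len <- floor(stats::runif(1, 1e4, 1e6))
          p1 <- floor(stats::runif(1, 1e4, cfg$genome[c1] - len - 1e4))
          recs[[i]] <- data.frame(sv_id = sprintf("%s_bg%03d", s, i),
                                  sample_id = s, sv_type = type[i], chrom1 = c1,
                                  pos1 = p1, chrom2 = c1, pos2 = p1 + len,
                                  quality = round(stats::runif(1, 20, 60)),
                                  support = 1L, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(recs)) do.call(rbind, recs) else empty_sv_calls()
  })
  names(sv) <- samples
  ## planted SVs: breakpoint inside the carrier's planted cluster span
  for (i in seq_len(nrow(carriers))) {
    g <- carriers$gene_id[i]; s <- carriers$sample_id[i]
    rows <- which(consensus$planted_gene %in% g)
    span <- c(min(consensus$start[rows]), max(consensus$end[rows]))
    chr <- consensus$chrom[rows[1]]
    bp <- floor(stats::runif(1, span[1], span[2]))
    len <- floor(stats::runif(1, 1e5, 1e6))
    typ <- sample(c("DEL", "DUP", "INV"), 1)
    rec <- data.frame(sv_id = sprintf("%s_pl_%s", s, g), sample_id = s,
                      sv_type = typ, chrom1 = chr, pos1 = bp, chrom2 = chr,
                      pos2 = bp + len, quality = 60, support = 1L,
                      stringsAsFactors = FALSE)
    sv[[s]] <- rbind(sv[[s]], rec)
  }

  ## --- expression -------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "expression"))
  mu <- stats::rnorm(cfg$n_genes, 5, 1)
  expr <- matrix(stats::rnorm(cfg$n_genes * length(samples), mu, cfg$noise_sd),
                 cfg$n_genes, length(samples),
                 dimnames = list(gene_models$gene_id, samples))
  for (g in planted_ids) {
    cars <- carriers$sample_id[carriers$gene_id == g]
    non <- setdiff(samples, cars)
    ## winsorize non-carriers at their own upper fence
    b <- iqr_upper_bound(expr[g, non])
    expr[g, non] <- pmin(expr[g, non], b$upper_bound)
    b <- iqr_upper_bound(expr[g, non])
    shifted <- expr[g, cars] + cfg$planted_effect * cfg$noise_sd
    expr[g, cars] <- pmax(shifted, b$q3 + 2 * b$iqr + 0.1)
  }

  ## --- clinical / survival ---------------------------------------------
  positive <- samples %in% unique(carriers$sample_id)
  names(positive) <- samples
  set.seed(sub_seed(cfg$seed, "survival"))
  rate <- cfg$baseline_hazard * ifelse(positive, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(length(samples), rate)
  t_cens <- stats::runif(length(samples), cfg$censor_range[1], cfg$censor_range[2])
  clinical <- data.frame(sample_id = samples, cohort = cohort,
                         rfs_time = round(pmin(t_event, t_cens), 2),
                         rfs_event = t_event <= t_cens,
                         stringsAsFactors = FALSE)

  list(peaks = peaks, sv = sv, peak_signal = sig,
       consensus_peaks = consensus[, c("chrom", "start", "end", "name")],
       expression = expr, gene_models = gene_models, clinical = clinical,
       truth = list(planted_genes = planted_ids, carriers = carriers,
                    positive = positive),
       config = cfg)
}

#' Write a synthetic cohort to disk
#'
#' Emits one narrowPeak file and one SV-VCF per sample, the consensus
#' peak-signal matrix, the expression matrix, the gene-model, clinical
#' and ground-truth tables, plus a manifest of md5 checksums. Everything
#' is plain text; with a fixed config the files are byte-identical
#' across runs.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return manifest \code{data.frame} with \code{file, md5}, invisibly
#'   also written to \code{manifest.tsv}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "sv"), showWarnings = FALSE)
  paths <- character()
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (s in names(cohort$peaks)) {
    p <- cohort$peaks[[s]]
    path <- file.path(dir, "peaks", paste0(s, ".narrowPeak"))
    writeLines(paste(p$chrom, fmt(p$start), fmt(p$end), p$name, "0", ".",
                     fmt(signif(p$signal, 8)), "-1", "-1", "-1", sep = "\t"),
               path)
    paths <- c(paths, path)
  }
  for (s in names(cohort$sv)) {
    path <- file.path(dir, "sv", paste0(s, ".vcf"))
    write_sv_vcf(cohort$sv[[s]], path)
    paths <- c(paths, path)
  }
  expr <- data.frame(gene_id = rownames(cohort$expression),
                     signif(cohort$expression, 8), check.names = FALSE)
  sig <- data.frame(peak_id = rownames(cohort$peak_signal),
                    signif(cohort$peak_signal, 8), check.names = FALSE)
  truth_carriers <- cohort$truth$carriers
  files <- list(expression.tsv = expr, peak_signal.tsv = sig,
                gene_models.tsv = cohort$gene_models[, c("gene_id", "symbol",
                  "chrom", "start", "end", "strand")],
                consensus_peaks.tsv = cohort$consensus_peaks,
                clinical.tsv = within(cohort$clinical,
                  rfs_event <- ifelse(rfs_event, "recurrence", "censored")),
                ground_truth_carriers.tsv = truth_carriers,
                ground_truth_genes.tsv = data.frame(
                  gene_id = cohort$truth$planted_genes))
  for (nm in names(files)) {
    path <- file.path(dir, nm)
    write_tsv(files[[nm]], path)
    paths <- c(paths, path)
  }
  manifest <- data.frame(file = sub(paste0("^", dir, "/?"), "", paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
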