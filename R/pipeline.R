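#' Default pipeline parameters
#'
#' Stage parameters with their conventional defaults: 12.5 kb stitching,
#' no TSS exclusion, 10 kb breakpoint flank (20 kb window), 1 kb
#' SURVIVOR-style merge distance with type matching, 50 kb gene
#' annotation flank, 0.5 Mb promoter distance for candidate links, 1000
#' permutations, FDR cut 0.05, LOF k = 10.
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(stitch_distance = 12500, tss_exclusion = 0, flank = 10000,
            merge_dist = 1000, require_type_match = TRUE,
            gene_flank = 50000, max_dist = 500000, B = 1000,
            fdr_cut = 0.05, lof_k = 10, seed = 1)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Run the integrated SE-SV analysis on an in-memory cohort
#'
#' Executes the full chain: per-sample super-enhancer calling, SV
#' consolidation and breakpoint windowing, SE-window intersection,
#' cohort frequency comparison, peak-to-gene links with permutation FDR,
#' the SE+SV gene filter, IQR outlier calling over the filtered genes,
#' and stratified recurrence-free survival.
#'
#' @param cohort list as produced by [generate_cohort()] (or assembled
#'   from [read_peaks()]/[read_sv_calls()]/... with the same element
#'   names).
#' @param params list from [pipeline_params()].
#' @param gene_set optional gene-id vector for the survival
#'   stratification; defaults to the genes surviving the SE+SV filter.
#' @return list with \code{se_calls, sv_consolidated, windows, overlaps,
#'   frequency, cohort_test, se_genes, sv_genes, links, filtered,
#'   outlier_calls, status, rfs, lof} (per-gene max LOF over the
#'   filtered genes' scatters, where defined).
#' @export
run_cohort_analysis <- function(cohort, params = pipeline_params(),
                                gene_set = NULL) {
  samples <- names(cohort$peaks)

  se_calls <- lapply(samples, function(s)
    call_super_enhancers(cohort$peaks[[s]], params$stitch_distance,
                         params$tss_exclusion,
                         if (params$tss_exclusion > 0) cohort$gene_models))
  names(se_calls) <- samples

  sv_cons <- lapply(samples, function(s)
    consolidate_calls(cohort$sv[[s]], params$merge_dist,
                      params$require_type_match))
  names(sv_cons) <- samples
  windows <- lapply(samples, function(s)
    make_windows(extract_breakpoints(sv_cons[[s]]), params$flank))
  names(windows) <- samples

  overlaps <- overlap_se_sv(do.call(rbind, se_calls),
                            do.call(rbind, windows))

  freq <- per_sample_frequency(overlaps, do.call(rbind, sv_cons),
                               cohort$clinical)
  cohort_test <- compare_cohort_frequencies(freq)

  se_ann <- annotate_overlap_genes(overlaps, cohort$gene_models,
                                   params$gene_flank)
  se_genes <- unique(se_ann$gene_id)
  ## SV-annotated genes: TSS within the annotation flank of any
  ## consolidated breakpoint
  bp_all <- do.call(rbind, lapply(sv_cons, extract_breakpoints))
  sv_genes <- unique(unlist(lapply(seq_len(nrow(cohort$gene_models)),
    function(g) {
      gm <- cohort$gene_models[g, ]
      hit <- norm_chrom(bp_all$chrom) == norm_chrom(gm$chrom) &
        abs(bp_all$pos - gm$tss) <= params$gene_flank
      if (any(hit)) gm$gene_id else NULL
    })))

  pairs <- candidate_pairs(cohort$consensus_peaks, cohort$gene_models,
                           params$max_dist)
  links <- link_pairs(pairs, cohort$peak_signal, cohort$expression,
                      B = params$B, seed = params$seed)
  filtered <- se_to_gene_filter(links, se_genes, sv_genes, params$fdr_cut)

  ## LOF / least-squares scatter scores for the filtered genes
  lof <- rep(NA_real_, nrow(filtered))
  n_samp <- length(intersect(colnames(cohort$peak_signal),
                             colnames(cohort$expression)))
  if (n_samp > params$lof_k) {
    common <- intersect(colnames(cohort$peak_signal),
                        colnames(cohort$expression))
    for (i in seq_len(nrow(filtered))) {
      x <- cohort$peak_signal[filtered$peak_id[i], common]
      y <- cohort$expression[filtered$gene_id[i], common]
      lof[i] <- max(lof_scores(x, y, k = params$lof_k))
    }
  }
  filtered$max_lof <- lof

  if (is.null(gene_set)) gene_set <- filtered$gene_id
  out_calls <- call_expression_outliers(cohort$expression, gene_set)
  status <- outlier_case_status(out_calls)
  rfs <- tryCatch(stratified_rfs(cohort$clinical, status),
                  error = function(e) NULL)

  list(se_calls = se_calls, sv_consolidated = sv_cons, windows = windows,
       overlaps = overlaps, frequency = freq, cohort_test = cohort_test,
       se_genes = se_genes, sv_genes = sv_genes, links = links,
       filtered = filtered, outlier_calls = out_calls, status = status,
       rfs = rfs)
}

#' Validate a file-based pipeline configuration
#'
#' @param config list with \code{peak_dir, sv_dir, expression,
#'   peak_signal, consensus_peaks, gene_models, clinical, out_dir} paths
#'   and optional \code{params} overrides (see [pipeline_params()]).
#' @return \code{data.frame} of diagnostics (\code{field, level,
#'   reason}); empty when the config is runnable.
#' @export
validate_config <- function(config) {
  diag <- list()
  add <- function(field, level, reason)
    diag[[length(diag) + 1L]] <<- data.frame(field = field, level = level,
                                             reason = reason,
                                             stringsAsFactors = FALSE)
  for (f in c("peak_dir", "sv_dir", "expression", "peak_signal",
              "consensus_peaks", "gene_models", "clinical")) {
    if (is.null(config[[f]])) add(f, "error", "missing path")
    else if (!file.exists(config[[f]])) add(f, "error",
                                            sprintf("path does not exist: %s", config[[f]]))
  }
  if (is.null(config$out_dir)) add("out_dir", "error", "missing path")
  p <- do.call(pipeline_params, config$params %||% list())
  if (p$B < 100) add("B", "warning", "fewer than 100 permutations is unreliable")
  for (f in c("flank", "stitch_distance", "merge_dist", "gene_flank",
              "max_dist"))
    if (p[[f]] < 0) add(f, "error", "must be non-negative")
  if (p$flank == 0) add("flank", "error", "breakpoint flank must be positive")
  if (p$fdr_cut <= 0 || p$fdr_cut > 1) add("fdr_cut", "error", "must lie in (0, 1]")
  if (length(diag)) do.call(rbind, diag) else
    data.frame(field = character(), level = character(), reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from files and write all stage outputs
#'
#' Reads the inputs named in \code{config}, runs
#' [run_cohort_analysis()], and writes per-stage TSV/BED artifacts plus
#' a JSON run manifest recording parameters, input checksums, the seed
#' and row counts. Reruns with an identical config are byte-identical.
#'
#' @param config see [validate_config()]; \code{peak_dir} holds one
#'   narrowPeak per sample (file name = sample id), \code{sv_dir} one
#'   \code{.vcf} per sample.
#' @return the manifest list, invisibly; artifacts land in
#'   \code{config$out_dir}.
#' @export
run_all <- function(config) {
  diag <- validate_config(config)
  if (any(diag$level == "error"))
    stop("invalid config:\n", paste(sprintf("  %s: %s", diag$field, diag$reason),
                                    collapse = "\n"))
  params <- do.call(pipeline_params, config$params %||% list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  peak_files <- sort(list.files(config$peak_dir, full.names = TRUE))
  sv_files <- sort(list.files(config$sv_dir, full.names = TRUE))
  sample_from <- function(f) sub("\\.[^.]*$", "", basename(f))
  cohort <- stage("read", {
    peaks <- lapply(peak_files, function(f) read_peaks(f, sample_from(f)))
    names(peaks) <- vapply(peak_files, sample_from, "")
    sv <- lapply(sv_files, function(f) read_sv_calls(f, sample_from(f), "sv-vcf"))
    names(sv) <- vapply(sv_files, sample_from, "")
    expression <- read_expression(config$expression)
    sig <- read_expression(config$peak_signal)  # same TSV layout
    cp <- utils::read.table(config$consensus_peaks, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    gm <- read_gene_models(config$gene_models)
    cl <- read_clinical(config$clinical, expression)
    if (!setequal(names(peaks), names(sv)))
      stop("peak and SV sample sets differ")
    list(peaks = peaks, sv = sv, expression = expression, peak_signal = sig,
         consensus_peaks = cp, gene_models = gm, clinical = cl)
  })
  res <- stage("analysis", run_cohort_analysis(cohort, params))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  se_all <- do.call(rbind, res$se_calls)
  stage("write", {
    write_bed(se_all, file.path(out, "se_calls.bed"),
              c("region_id", "total_signal", "rank", "is_super"))
    win_all <- do.call(rbind, res$windows)
    if (nrow(win_all)) win_all$sample_id <- as.character(win_all$sample_id)
    write_bed(win_all, file.path(out, "sv_windows.bed"),
              c("sv_id", "breakpoint_pos", "sample_id"))
    write_tsv(res$overlaps, file.path(out, "overlaps.tsv"))
    write_tsv(res$frequency, file.path(out, "frequency.tsv"))
    write_tsv(res$cohort_test, file.path(out, "cohort_test.tsv"))
    write_tsv(res$links, file.path(out, "links.tsv"))
    write_tsv(res$filtered, file.path(out, "se_to_gene.tsv"))
    write_tsv(res$outlier_calls, file.path(out, "outlier_calls.tsv"))
    if (!is.null(res$rfs))
      write_tsv(data.frame(stratum = c("positive", "negative"),
                           n = c(res$rfs$n_pos, res$rfs$n_neg),
                           chi2 = res$rfs$chi2, p = res$rfs$p),
                file.path(out, "rfs_test.tsv"))
  })
  artifacts <- sort(list.files(out, full.names = TRUE))
  artifacts <- artifacts[basename(artifacts) != "run_manifest.json"]
  manifest <- list(
    parameters = params,
    inputs = as.list(tools::md5sum(c(config$expression, config$peak_signal,
                                     config$consensus_peaks,
                                     config$gene_models, config$clinical))),
    n_samples = length(res$se_calls),
    rows = list(se_calls = nrow(se_all), overlaps = nrow(res$overlaps),
                links = nrow(res$links), se_to_gene = nrow(res$filtered)),
    outputs = as.list(tools::md5sum(artifacts)))
  names(manifest$inputs) <- basename(names(manifest$inputs))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
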