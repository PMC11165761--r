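#' Candidate peak-gene pairs within a promoter distance
#'
#' A consensus peak is paired with a gene when the minimum distance from
#' the peak interval to the gene's TSS is at most \code{max_dist} bp
#' (default 0.5 Mb). A TSS inside the peak has distance 0.
#'
#' @param peaks consensus peak \code{data.frame} with \code{chrom, start,
#'   end, name}; \code{name} is used as the peak id.
#' @param gene_models gene-model table (see [read_gene_models()]).
#' @param max_dist maximum peak-to-TSS distance in bp (default 500000).
#' @return \code{data.frame} with \code{peak_id, gene_id, symbol,
#'   distance_to_tss}.
#' @export
candidate_pairs <- function(peaks, gene_models, max_dist = 500000) {
  out <- list()
  pk_chr <- norm_chrom(peaks$chrom)
  for (g in seq_len(nrow(gene_models))) {
    tss <- gene_models$tss[g]
    same <- pk_chr == norm_chrom(gene_models$chrom[g])
    ## covered positions are start .. end-1 (half-open)
    d <- pmax(0, peaks$start - tss, tss - (peaks$end - 1))
    hit <- same & d <= max_dist
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        peak_id = peaks$name[hit], gene_id = gene_models$gene_id[g],
        symbol = gene_models$symbol[g], distance_to_tss = d[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak_id = character(), gene_id = character(),
                      symbol = character(), distance_to_tss = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$peak_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pearson correlation for one peak-gene link
#'
#' Plain product-moment correlation between a peak's per-sample signal
#' and a gene's per-sample expression, matching the straight-line fit
#' used for the scatter display. Zero variance on either side leaves the
#' correlation undefined and the link is dropped upstream.
#'
#' @param x,y numeric vectors over the same samples, length >= 3.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return correlation in \[-1, 1\], or \code{NA} when undefined.
#' @export
pearson_link <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in link vectors")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Permutation p-value for a peak-gene correlation
#'
#' Permutes the sample labels of \code{y} B times and computes the
#' two-sided empirical p-value with the add-one estimator
#' \code{p = (1 + #\{|r_b| >= |r_obs|\}) / (B + 1)}, whose attainable
#' minimum is \code{1/(B+1)}.
#'
#' @param x,y numeric vectors over the same samples.
#' @param B number of permutations (default 1000; at least 100).
#' @param seed optional integer seed for the permutation stream.
#' @param perm_idx optional precomputed n-by-B matrix of permutation
#'   indices, shared across links of one run for speed; overrides
#'   \code{B}/\code{seed}.
#' @param method correlation method, see [pearson_link()].
#' @return list with \code{r} (observed), \code{p}, and \code{null}
#'   (the B permuted correlations).
#' @export
permutation_null_p <- function(x, y, B = 1000, seed = NULL, perm_idx = NULL,
                               method = "pearson") {
  r_obs <- pearson_link(x, y, method)
  if (is.na(r_obs)) return(list(r = NA_real_, p = NA_real_, null = numeric()))
  n <- length(x)
  if (is.null(perm_idx)) {
    if (B < 100L) stop("B must be at least 100")
    if (!is.null(seed)) set.seed(seed)
    perm_idx <- replicate(B, sample.int(n))
  }
  B <- ncol(perm_idx)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  null <- colSums(xs * matrix(ys[perm_idx], n, B)) / (n - 1)
  p <- (1 + sum(abs(null) >= abs(r_obs))) / (B + 1)
  list(r = r_obs, p = p, null = null)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}) with the usual
#' monotonicity enforcement and capping at 1.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Correlate all candidate pairs and attach the permutation FDR
#'
#' Runs [pearson_link()] and [permutation_null_p()] over every candidate
#' pair, drops undefined links (zero variance) with a note, and adjusts
#' the permutation p-values with [bh_fdr()] across the retained links.
#'
#' @param pairs candidate pairs from [candidate_pairs()].
#' @param peak_signal peaks-by-samples numeric matrix (rownames =
#'   peak ids).
#' @param expression genes-by-samples numeric matrix (rownames =
#'   gene ids); columns are aligned to \code{peak_signal} by name.
#' @param B permutations per link (default 1000).
#' @param seed integer seed for the shared permutation stream.
#' @param method correlation method, see [pearson_link()].
#' @return \code{data.frame}: pairs plus \code{r, p, fdr}.
#' @export
link_pairs <- function(pairs, peak_signal, expression, B = 1000, seed = 1,
                       method = "pearson") {
  common <- intersect(colnames(peak_signal), colnames(expression))
  if (length(common) < 3L) stop("fewer than 3 shared samples between matrices")
  ps <- peak_signal[, common, drop = FALSE]
  ex <- expression[, common, drop = FALSE]
  n <- length(common)
  set.seed(seed)
  perm_idx <- replicate(B, sample.int(n))
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- ps[pairs$peak_id[i], ]
    y <- ex[pairs$gene_id[i], ]
    res <- permutation_null_p(x, y, perm_idx = perm_idx, method = method)
    r[i] <- res$r; p[i] <- res$p
  }
  dropped <- is.na(r)
  if (any(dropped))
    message(sprintf("note: %d link(s) dropped (zero-variance signal or expression)",
                    sum(dropped)))
  out <- cbind(pairs[!dropped, , drop = FALSE],
               r = r[!dropped], p = p[!dropped])
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Filter links to SE- and SV-annotated genes and rank by FDR
#'
#' Keeps links with \code{fdr < fdr_cut} whose gene is annotated both to
#' a super-enhancer region and to a structural variant, collapses to one
#' row per gene (best FDR, ties by |r| descending), and sorts ascending
#' by FDR (ties by |r| descending, then symbol).
#'
#' @param links link table from [link_pairs()].
#' @param se_genes character vector of SE-annotated gene ids.
#' @param sv_genes character vector of SV-annotated gene ids.
#' @param fdr_cut FDR threshold (default 0.05, strict inequality).
#' @return ranked per-gene \code{data.frame} with added \code{in_se},
#'   \code{has_sv} columns (both \code{TRUE} by construction).
#' @export
se_to_gene_filter <- function(links, se_genes, sv_genes, fdr_cut = 0.05) {
  keep <- links$fdr < fdr_cut & links$gene_id %in% se_genes &
    links$gene_id %in% sv_genes
  res <- links[keep, , drop = FALSE]
  if (nrow(res)) {
    res <- res[order(res$gene_id, res$fdr, -abs(res$r)), , drop = FALSE]
    res <- res[!duplicated(res$gene_id), , drop = FALSE]
    res <- res[order(res$fdr, -abs(res$r), res$symbol), , drop = FALSE]
  }
  res$in_se <- rep(TRUE, nrow(res))
  res$has_sv <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}

#' Ordinary least-squares line through a scatter
#'
#' @param x,y numeric vectors, length >= 2; \code{x} must not be
#'   constant.
#' @return list with \code{slope} and \code{intercept}.
#' @export
least_squares_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0) stop("least_squares_fit: x is constant")
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Local outlier factor scores
#'
#' Classic LOF: for each point, the k-distance neighborhood (including
#' all neighbors tied at the k-distance), reachability distances, local
#' reachability density, and the LOF as the mean ratio of neighbor
#' density to own density. Scores near 1 indicate homogeneous density;
#' scores well above 1 indicate isolation. Because peak signal and
#' expression are on incommensurate scales, coordinates are z-scored per
#' axis before Euclidean distances (disable with
#' \code{standardize = FALSE}).
#'
#' @param x,y numeric coordinate vectors (e.g. peak signal and
#'   expression per sample).
#' @param k neighborhood size (default 10); requires \code{n >= k + 1}.
#' @param standardize z-score each axis first (default \code{TRUE}).
#' @return numeric vector of LOF scores, one per point.
#' @export
lof_scores <- function(x, y, k = 10, standardize = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= k) stop(sprintf("lof_scores: need n >= k + 1 (n = %d, k = %d)", n, k))
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)
  pts <- if (standardize) cbind(zs(x), zs(y)) else cbind(x, y)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  kdist <- apply(d, 1, function(r) sort(r)[k])
  ## k-distance neighborhoods, ties included
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= kdist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
    m <- mean(reach)
    if (m == 0) Inf else 1 / m
  }, 0)
  vapply(seq_len(n), function(i) {
    ratio <- lrd[nbrs[[i]]] / lrd[i]
    ratio[is.nan(ratio)] <- 1   # Inf/Inf: duplicated points share density
    mean(ratio)
  }, 0)
}

#' Associate SV presence with expression shifts per gene
#'
#' For each gene with at least 2 carrier and 2 non-carrier samples, a
#' two-sided equal-variance t-test of carriers vs non-carriers, BH
#' adjustment across tested genes, and a call of elevated / decreased by
#' the sign of the mean difference at \code{fdr < 0.05}; everything else
#' is unchanged.
#'
#' @param expression genes-by-samples matrix.
#' @param sv_carriers \code{data.frame} with \code{gene_id, sample_id}
#'   rows marking carrier samples.
#' @param fdr_cut significance threshold (default 0.05).
#' @return \code{data.frame} with \code{gene_id, n_carrier, mean_diff,
#'   p, fdr, status}.
#' @export
sv_expression_association <- function(expression, sv_carriers, fdr_cut = 0.05) {
  genes <- rownames(expression)
  carriers <- split(sv_carriers$sample_id, sv_carriers$gene_id)
  p <- diff <- rep(NA_real_, length(genes))
  ncar <- integer(length(genes))
  for (i in seq_along(genes)) {
    car <- intersect(carriers[[genes[i]]], colnames(expression))
    ncar[i] <- length(car)
    non <- setdiff(colnames(expression), car)
    if (length(car) < 2L || length(non) < 2L) next
    a <- expression[i, car]; b <- expression[i, non]
    if (stats::sd(c(a, b)) == 0) { p[i] <- 1; diff[i] <- 0; next }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    p[i] <- tt$p.value
    diff[i] <- mean(a) - mean(b)
  }
  tested <- !is.na(p)
  fdr <- rep(NA_real_, length(genes))
  fdr[tested] <- bh_fdr(p[tested])
  status <- rep("unchanged", length(genes))
  status[tested & fdr < fdr_cut & diff > 0] <- "elevated"
  status[tested & fdr < fdr_cut & diff < 0] <- "decreased"
  data.frame(gene_id = genes, n_carrier = ncar, mean_diff = diff,
             p = p, fdr = fdr, status = status, stringsAsFactors = FALSE)
}
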