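#' IQR upper outlier bound
#'
#' Quartiles by linear interpolation (R's default type-7 convention) and
#' the upper fence \code{Q3 + 1.5 * IQR}. Only the upper tail is fenced:
#' the analysis targets aberrant over-expression.
#'
#' @param values numeric vector, length >= 4.
#' @return list with \code{q1, q3, iqr, upper_bound}.
#' @export
iqr_upper_bound <- function(values) {
  if (length(values) < 4L)
    stop("iqr_upper_bound: need at least 4 values")
  if (any(!is.finite(values))) stop("iqr_upper_bound: non-finite values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr, upper_bound = q[2] + 1.5 * iqr)
}

#' Call expression outliers per gene over a gene set
#'
#' For each gene in the set present in the matrix, the upper bound is
#' computed across all samples and every sample strictly above it is
#' flagged. Genes missing from the matrix are noted and skipped.
#'
#' @param expression genes-by-samples matrix (rownames are matched first
#'   against gene ids, i.e. rownames, then left as-is; pass symbols as
#'   rownames when working with symbol gene sets).
#' @param gene_set character vector of gene ids / symbols.
#' @return \code{data.frame} with \code{gene_id, sample_id, value, q1,
#'   q3, iqr, upper_bound, is_outlier}, one row per (gene, sample).
#' @export
call_expression_outliers <- function(expression, gene_set) {
  present <- intersect(gene_set, rownames(expression))
  missing <- setdiff(gene_set, present)
  if (length(missing))
    message(sprintf("note: %d gene(s) of the set missing from the matrix: %s",
                    length(missing), paste(utils::head(missing, 10), collapse = ", ")))
  out <- vector("list", length(present))
  for (i in seq_along(present)) {
    v <- expression[present[i], ]
    b <- iqr_upper_bound(v)
    out[[i]] <- data.frame(gene_id = present[i],
                           sample_id = colnames(expression),
                           value = as.numeric(v), q1 = b$q1, q3 = b$q3,
                           iqr = b$iqr, upper_bound = b$upper_bound,
                           is_outlier = as.numeric(v) > b$upper_bound,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), sample_id = character(),
               value = numeric(), q1 = numeric(), q3 = numeric(),
               iqr = numeric(), upper_bound = numeric(),
               is_outlier = logical())
  rownames(res) <- NULL
  res
}

#' Per-case outlier status over a gene set
#'
#' A case is outlier-positive when at least one gene of the set is an
#' expression outlier in that case.
#'
#' @param calls outlier calls from [call_expression_outliers()].
#' @return named logical vector over the samples appearing in
#'   \code{calls}.
#' @export
outlier_case_status <- function(calls) {
  if (nrow(calls) == 0L) return(setNames(logical(), character()))
  spl <- split(calls$is_outlier, calls$sample_id)
  vapply(spl[unique(calls$sample_id)], any, TRUE)
}

#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper over \code{survival::survfit}; subjects censored at t are
#' still at risk at t, per the standard convention.
#'
#' @param times non-negative follow-up times (months).
#' @param events logical (or 0/1) event indicators, \code{TRUE} =
#'   recurrence.
#' @return \code{data.frame} with \code{time, n_risk, n_event, n_censor,
#'   surv} at each observed time.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard unweighted 1-df log-rank chi-square (via
#' \code{survival::survdiff}) with the p-value from the upper chi-square
#' tail.
#'
#' @param times,events follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return list with \code{chi2} and \code{p}.
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_test: exactly two groups required")
  if (sum(as.integer(events)) == 0L) stop("logrank_test: no events observed")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Stratify recurrence-free survival by outlier status
#'
#' Kaplan-Meier curves for outlier-positive and outlier-negative cases
#' plus the log-rank comparison.
#'
#' @param clinical clinical \code{data.frame} (see [read_clinical()]);
#'   rows without follow-up are dropped.
#' @param status named logical vector from [outlier_case_status()] (or
#'   any per-sample labelling); samples absent from \code{status} are
#'   treated as negative.
#' @return list with \code{curve_pos}, \code{curve_neg}, \code{chi2},
#'   \code{p}, \code{n_pos}, \code{n_neg}.
#' @export
stratified_rfs <- function(clinical, status) {
  cl <- clinical[!is.na(clinical$rfs_time), , drop = FALSE]
  pos <- cl$sample_id %in% names(status)[status]
  if (!any(pos)) stop("stratified_rfs: the outlier-positive stratum is empty")
  if (all(pos)) stop("stratified_rfs: the outlier-negative stratum is empty")
  lr <- logrank_test(cl$rfs_time, cl$rfs_event, pos)
  list(curve_pos = km_estimate(cl$rfs_time[pos], cl$rfs_event[pos]),
       curve_neg = km_estimate(cl$rfs_time[!pos], cl$rfs_event[!pos]),
       chi2 = lr$chi2, p = lr$p, n_pos = sum(pos), n_neg = sum(!pos))
}

#' Per-gene outlier prevalence among positive cases
#'
#' For each gene of the set, the fraction of outlier-positive cases in
#' which that gene is an outlier (the radar-chart quantity).
#'
#' @param calls outlier calls from [call_expression_outliers()].
#' @param gene_set genes to report (default: genes present in
#'   \code{calls}).
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
outlier_prevalence <- function(calls, gene_set = NULL) {
  status <- outlier_case_status(calls)
  pos <- names(status)[status]
  if (length(pos) == 0L) stop("outlier_prevalence: no outlier-positive cases")
  if (is.null(gene_set)) gene_set <- unique(calls$gene_id)
  vapply(setNames(gene_set, gene_set), function(g) {
    hit <- calls$sample_id[calls$gene_id == g & calls$is_outlier]
    length(intersect(hit, pos)) / length(pos)
  }, 0)
}

#' The named outlier gene sets
#'
#' \code{"top6"} is the prioritized driver set CDK4, ERBB2, MDM2, FRS2,
#' EGFR, CAV2; larger sets (e.g. the 26-gene SE-to-gene table) are
#' supplied by the user as a character vector or one-symbol-per-line
#' file.
#'
#' @param name \code{"top6"}, a character vector of symbols, or a path
#'   to a one-symbol-per-line file.
#' @return character vector of gene symbols.
#' @export
outlier_gene_set <- function(name = "top6") {
  if (length(name) > 1L) return(as.character(name))
  if (identical(name, "top6"))
    return(c("CDK4", "ERBB2", "MDM2", "FRS2", "EGFR", "CAV2"))
  if (file.exists(name)) {
    g <- trimws(readLines(name))
    return(g[nzchar(g)])
  }
  as.character(name)
}
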