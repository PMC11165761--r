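#' Consolidate structural-variant calls within a sample
#'
#' SURVIVOR-style merging: two calls are merged when their breakpoints
#' agree positionwise within \code{max_dist} bp on matching chromosomes
#' (and, if \code{require_type_match}, share the SV type). Merging is
#' transitive (single-linkage over the pair graph); the representative
#' of a merged group is its member with the smallest
#' (\code{chrom1, pos1, pos2}) and carries the group's support count.
#'
#' @param calls SV call \code{data.frame} from one sample (see
#'   [read_sv_calls()]).
#' @param max_dist maximum per-breakpoint distance in bp (default 1000,
#'   mirroring common SURVIVOR usage).
#' @param require_type_match merge only calls of the same type (default
#'   \code{TRUE}).
#' @return consolidated call \code{data.frame}; \code{support} holds the
#'   number of input calls behind each record. Output order is
#'   deterministic (sorted by chrom1, pos1, pos2, sv_id) regardless of
#'   input order.
#' @export
consolidate_calls <- function(calls, max_dist = 1000, require_type_match = TRUE) {
  n <- nrow(calls)
  if (n == 0L) return(calls)
  validate_sv_calls(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  mate_chrom <- ifelse(is.na(calls$chrom2), calls$chrom1, calls$chrom2)
  mate_pos <- ifelse(is.na(calls$pos2), calls$pos1, calls$pos2)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (require_type_match && calls$sv_type[i] != calls$sv_type[j]) next
    if (norm_chrom(calls$chrom1[i]) != norm_chrom(calls$chrom1[j])) next
    if (norm_chrom(mate_chrom[i]) != norm_chrom(mate_chrom[j])) next
    if (abs(calls$pos1[i] - calls$pos1[j]) > max_dist) next
    if (abs(mate_pos[i] - mate_pos[j]) > max_dist) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), root)
  reps <- lapply(groups, function(idx) {
    g <- calls[idx, , drop = FALSE]
    o <- order(g$chrom1, g$pos1, ifelse(is.na(g$pos2), g$pos1, g$pos2), g$sv_id)
    rep_row <- g[o[1], , drop = FALSE]
    rep_row$support <- sum(g$support)
    rep_row
  })
  res <- do.call(rbind, reps)
  o <- order(res$chrom1, res$pos1, ifelse(is.na(res$pos2), res$pos1, res$pos2),
             res$sv_id)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate the breakends of SV calls
#'
#' DEL/DUP/INV/TRA contribute both breakends; an insertion with only one
#' recorded position contributes one.
#'
#' @param calls SV call \code{data.frame}.
#' @return \code{data.frame} with \code{sv_id, sample_id, chrom, pos},
#'   one row per breakend.
#' @export
extract_breakpoints <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(sv_id = character(), sample_id = character(),
                      chrom = character(), pos = numeric()))
  validate_sv_calls(calls)
  first <- data.frame(sv_id = calls$sv_id, sample_id = calls$sample_id,
                      chrom = calls$chrom1, pos = calls$pos1,
                      stringsAsFactors = FALSE)
  has2 <- !is.na(calls$pos2)
  second <- data.frame(sv_id = calls$sv_id[has2],
                       sample_id = calls$sample_id[has2],
                       chrom = calls$chrom2[has2], pos = calls$pos2[has2],
                       stringsAsFactors = FALSE)
  res <- rbind(first, second)
  res <- res[order(res$chrom, res$pos, res$sv_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build breakpoint windows for overlap testing
#'
#' Each breakend becomes the interval \code{[max(0, pos - flank),
#' pos + flank)} — with the default 10 kb flank, the 20 kb region
#' surrounding the breakpoint that is intersected with super-enhancers.
#' Windows are clipped at position 0.
#'
#' @param breakpoints \code{data.frame} from [extract_breakpoints()].
#' @param flank half-width in bp (default 10000).
#' @return \code{data.frame} with \code{chrom, start, end, sv_id,
#'   breakpoint_pos, sample_id}.
#' @export
make_windows <- function(breakpoints, flank = 10000) {
  stopifnot(flank > 0)
  if (nrow(breakpoints) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sv_id = character(), breakpoint_pos = numeric(),
                      sample_id = character()))
  data.frame(chrom = breakpoints$chrom,
             start = pmax(0, breakpoints$pos - flank),
             end = breakpoints$pos + flank,
             sv_id = breakpoints$sv_id,
             breakpoint_pos = breakpoints$pos,
             sample_id = breakpoints$sample_id,
             stringsAsFactors = FALSE)
}
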