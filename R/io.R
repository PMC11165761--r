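#' Read H3K27Ac peak calls from BED / narrowPeak
#'
#' Accepts ENCODE narrowPeak (10 columns, signalValue in column 7) or
#' BED3+score. Coordinates in these formats are already 0-based half-open
#' and are kept verbatim. Rows come back sorted by (chrom, start, end).
#'
#' @param path tab-separated peak file; \code{#}-prefixed and "track"
#'   header lines are skipped.
#' @param sample_id sample identifier attached to every row.
#' @param signal_col 1-based column holding the signal; default picks
#'   column 7 (narrowPeak signalValue) when present, else column 5.
#' @return \code{data.frame} with \code{chrom, start, end, name, signal,
#'   sample_id}.
#' @export
read_peaks <- function(path, sample_id, signal_col = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), signal = numeric(),
                      sample_id = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed peak line %d in %s: fewer than 3 fields",
                 lineno[which(nf < 3L)[1]], path))
  ncol_min <- min(nf)
  if (is.null(signal_col)) signal_col <- if (ncol_min >= 7L) 7L else 5L
  if (ncol_min < signal_col)
    stop(sprintf("peak file %s has %d columns; signal column %d requested",
                 path, ncol_min, signal_col))
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  signal <- suppressWarnings(as.numeric(get(signal_col)))
  bad <- which(is.na(start) | is.na(end) | is.na(signal))
  if (length(bad))
    stop(sprintf("malformed peak line %d in %s: non-numeric coordinate or signal",
                 lineno[bad[1]], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("rejected peak record at line %d in %s: start >= end",
                 lineno[bad[1]], path))
  if (any(signal < 0))
    stop(sprintf("rejected peak record at line %d in %s: negative signal",
                 lineno[which(signal < 0)[1]], path))
  name <- if (ncol_min >= 4L) get(4) else sprintf("peak_%d", seq_along(start))
  df <- data.frame(chrom = get(1), start = start, end = end, name = name,
                   signal = signal, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

sv_types <- c("DEL", "DUP", "INV", "TRA", "INS")

validate_sv_calls <- function(sv) {
  intra <- sv$sv_type %in% c("DEL", "DUP", "INV")
  bad <- which(intra & (sv$chrom1 != sv$chrom2 | sv$pos1 >= sv$pos2))
  if (length(bad))
    stop(sprintf("invalid %s call %s: need chrom1 == chrom2 and pos1 < pos2",
                 sv$sv_type[bad[1]], sv$sv_id[bad[1]]))
  bad <- which(sv$sv_type == "TRA" & sv$chrom1 == sv$chrom2)
  if (length(bad))
    stop(sprintf("invalid TRA call %s: breakends on the same chromosome",
                 sv$sv_id[bad[1]]))
  invisible(sv)
}

#' Read structural-variant calls
#'
#' Two dialects are supported. \code{"sv-vcf"}: Manta-style VCF records
#' with \code{SVTYPE} and \code{END} (intra-chromosomal) or
#' \code{CHR2}/\code{POS2} (translocations) INFO keys; 1-based VCF
#' positions become internal 0-based breakends (\code{bp1 = POS - 1},
#' \code{bp2 = END} read as the half-open right edge). \code{"bedpe"}:
#' 6 coordinate columns (already 0-based) plus name/score/strands and the
#' SV type in column 11 (or column 7 of a minimal file). Records with an
#' unknown SVTYPE are skipped with a warning; a TRA without a mate
#' coordinate is an error.
#'
#' @param path input file.
#' @param sample_id sample identifier attached to every call.
#' @param dialect \code{"sv-vcf"} or \code{"bedpe"}.
#' @return \code{data.frame} with \code{sv_id, sample_id, sv_type, chrom1,
#'   pos1, chrom2, pos2, quality, support}. \code{pos2}/\code{chrom2} are
#'   \code{NA} for single-breakend insertions.
#' @export
read_sv_calls <- function(path, sample_id, dialect = c("sv-vcf", "bedpe")) {
  dialect <- match.arg(dialect)
  if (dialect == "sv-vcf") read_sv_vcf(path, sample_id)
  else read_sv_bedpe(path, sample_id)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0,
         sub(paste0(".*", key, "="), "", m), NA_character_)
}

read_sv_vcf <- function(path, sample_id) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  out <- vector("list", length(body))
  skipped <- 0L
  for (k in seq_along(body)) {
    i <- body[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed VCF line %d in %s: fewer than 8 fields", i, path))
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos))
      stop(sprintf("malformed VCF line %d in %s: non-numeric POS", i, path))
    info <- f[8]
    svtype <- info_field(info, "SVTYPE")
    if (is.na(svtype) || !(svtype %in% sv_types)) {
      warning(sprintf("skipping VCF line %d in %s: unknown SVTYPE '%s'",
                      i, path, if (is.na(svtype)) "" else svtype))
      skipped <- skipped + 1L
      next
    }
    endv <- suppressWarnings(as.numeric(info_field(info, "END")))
    chr2 <- info_field(info, "CHR2")
    pos2 <- suppressWarnings(as.numeric(info_field(info, "POS2")))
    qual <- suppressWarnings(as.numeric(f[6]))
    id <- if (f[3] == "." || !nzchar(f[3])) sprintf("%s_sv%d", sample_id, k) else f[3]
    if (svtype == "TRA") {
      if (is.na(chr2) || is.na(pos2))
        stop(sprintf("rejected TRA record at VCF line %d in %s: missing mate coordinate (CHR2/POS2)",
                     i, path))
      rec <- data.frame(sv_id = id, sample_id = sample_id, sv_type = svtype,
                        chrom1 = f[1], pos1 = pos - 1, chrom2 = chr2,
                        pos2 = pos2 - 1, quality = qual, support = 1L,
                        stringsAsFactors = FALSE)
    } else if (svtype == "INS") {
      rec <- data.frame(sv_id = id, sample_id = sample_id, sv_type = svtype,
                        chrom1 = f[1], pos1 = pos - 1, chrom2 = NA_character_,
                        pos2 = NA_real_, quality = qual, support = 1L,
                        stringsAsFactors = FALSE)
    } else {
      if (is.na(endv))
        stop(sprintf("rejected %s record at VCF line %d in %s: missing END",
                     svtype, i, path))
      rec <- data.frame(sv_id = id, sample_id = sample_id, sv_type = svtype,
                        chrom1 = f[1], pos1 = pos - 1, chrom2 = f[1],
                        pos2 = endv, quality = qual, support = 1L,
                        stringsAsFactors = FALSE)
    }
    out[[k]] <- rec
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty_sv_calls()
  validate_sv_calls(res)
  res
}

read_sv_bedpe <- function(path, sample_id) {
  lines <- readLines(path)
  body <- which(!grepl("^(#|track)", lines) & nzchar(trimws(lines)))
  out <- vector("list", length(body))
  for (k in seq_along(body)) {
    i <- body[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 7L)
      stop(sprintf("malformed BEDPE line %d in %s: need 6 coordinate columns plus type",
                   i, path))
    type_col <- if (length(f) >= 11L) 11L else 7L
    svtype <- f[type_col]
    if (!(svtype %in% sv_types)) {
      warning(sprintf("skipping BEDPE line %d in %s: unknown SV type '%s'",
                      i, path, svtype))
      next
    }
    s1 <- suppressWarnings(as.numeric(f[2])); e1 <- suppressWarnings(as.numeric(f[3]))
    s2 <- suppressWarnings(as.numeric(f[5])); e2 <- suppressWarnings(as.numeric(f[6]))
    if (anyNA(c(s1, e1, s2, e2)))
      stop(sprintf("malformed BEDPE line %d in %s: non-numeric coordinate", i, path))
    id <- if (length(f) >= 7L && type_col == 11L && nzchar(f[7]) && f[7] != ".")
      f[7] else sprintf("%s_sv%d", sample_id, k)
    ## breakend = last base of the 1 bp BEDPE anchor interval, 0-based
    out[[k]] <- data.frame(sv_id = id, sample_id = sample_id, sv_type = svtype,
                           chrom1 = f[1], pos1 = e1 - 1,
                           chrom2 = if (svtype == "INS" && f[4] == ".") NA_character_ else f[4],
                           pos2 = if (svtype == "INS" && f[4] == ".") NA_real_ else e2 - 1,
                           quality = NA_real_, support = 1L,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty_sv_calls()
  validate_sv_calls(res)
  res
}

empty_sv_calls <- function() {
  data.frame(sv_id = character(), sample_id = character(),
             sv_type = character(), chrom1 = character(), pos1 = numeric(),
             chrom2 = character(), pos2 = numeric(), quality = numeric(),
             support = integer(), stringsAsFactors = FALSE)
}

#' Write structural-variant calls as a minimal SV-VCF
#'
#' Inverse of [read_sv_calls()] for the \code{"sv-vcf"} dialect: internal
#' 0-based breakends become \code{POS = bp1 + 1} and \code{END = bp2}
#' (\code{CHR2}/\code{POS2} for translocations). Plain text, never
#' compressed.
#'
#' @param sv SV call \code{data.frame} (see [read_sv_calls()]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sv_vcf <- function(sv, path) {
  validate_sv_calls(sv)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
           "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Mate position\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Merged call support\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- character(nrow(sv))
  for (i in seq_len(nrow(sv))) {
    parts <- paste0("SVTYPE=", sv$sv_type[i])
    if (sv$sv_type[i] == "TRA") {
      parts <- c(parts, paste0("CHR2=", sv$chrom2[i]),
                 paste0("POS2=", format(sv$pos2[i] + 1, scientific = FALSE)))
    } else if (sv$sv_type[i] != "INS") {
      parts <- c(parts, paste0("END=", format(sv$pos2[i], scientific = FALSE)))
    }
    parts <- c(parts, paste0("SUPPORT=", sv$support[i]))
    info[i] <- paste(parts, collapse = ";")
  }
  qual <- ifelse(is.na(sv$quality), ".", format(sv$quality, scientific = FALSE))
  rows <- paste(sv$chrom1, format(sv$pos1 + 1, scientific = FALSE, trim = TRUE),
                sv$sv_id, "N", paste0("<", sv$sv_type, ">"), qual, "PASS", info,
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Values are taken as log-scale abundance by convention and are not
#' re-normalized.
#'
#' @param path TSV file.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop(sprintf("duplicate gene id '%s' in %s", df[[1]][duplicated(df[[1]])][1], path))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate sample id in %s", path))
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a gene-model table
#'
#' TSV with header columns \code{gene_id, symbol, chrom, start, end,
#' strand}; coordinates 0-based half-open. The TSS is derived from the
#' strand: \code{start} for \code{"+"}, \code{end - 1} for \code{"-"}.
#'
#' @param path TSV file.
#' @return \code{data.frame} with an added \code{tss} column.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop(sprintf("gene-model table %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(df$gene_id))
    stop(sprintf("duplicate gene id in %s", path))
  validate_intervals(df)
  df$tss <- ifelse(df$strand == "-", df$end - 1, df$start)
  df
}

#' Read a clinical table
#'
#' TSV with header columns \code{sample_id, cohort, rfs_time, rfs_event}.
#' \code{cohort} is \code{CAGA} or \code{non-CAGA}; \code{rfs_time} is in
#' months; \code{rfs_event} accepts 0/1 or censored/recurrence and is
#' returned as logical (\code{TRUE} = recurrence). Time and event must be
#' jointly present or jointly missing per sample.
#'
#' @param path TSV file.
#' @param expression optional expression matrix used to cross-check
#'   sample ids; mismatches are reported as a message, not an error, so
#'   non-survival stages can still use the extra samples.
#' @return \code{data.frame(sample_id, cohort, rfs_time, rfs_event)}.
#' @export
read_clinical <- function(path, expression = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "cohort", "rfs_time", "rfs_event")
  if (!all(need %in% names(df)))
    stop(sprintf("clinical table %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample id in %s", path))
  if (!all(df$cohort %in% c("CAGA", "non-CAGA")))
    stop(sprintf("unknown cohort label in %s (expect CAGA / non-CAGA)", path))
  ev <- df$rfs_event
  event <- rep(NA, nrow(df))
  event[ev %in% c("1", 1, "recurrence")] <- TRUE
  event[ev %in% c("0", 0, "censored")] <- FALSE
  if (any(!is.na(ev) & is.na(event)))
    stop(sprintf("unparseable rfs_event value '%s' in %s",
                 ev[!is.na(ev) & is.na(event)][1], path))
  if (any(is.na(df$rfs_time) != is.na(event)))
    stop(sprintf("sample %s in %s has rfs_time without rfs_event (or vice versa)",
                 df$sample_id[is.na(df$rfs_time) != is.na(event)][1], path))
  if (any(!is.na(df$rfs_time) & df$rfs_time < 0))
    stop(sprintf("negative rfs_time in %s", path))
  df$rfs_event <- event
  if (!is.null(expression)) {
    extra <- setdiff(colnames(expression), df$sample_id)
    if (length(extra))
      message(sprintf("note: %d expression sample(s) missing from clinical table (retained for non-survival stages): %s",
                      length(extra), paste(utils::head(extra, 5), collapse = ", ")))
  }
  df
}

#' Write an interval table as BED
#'
#' @param df data.frame with \code{chrom, start, end} plus optional extra
#'   columns appended in order.
#' @param path output file.
#' @param extra_cols character vector of additional column names to write
#'   after the three coordinates.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(df, path, extra_cols = character()) {
  validate_intervals(df)
  cols <- c("chrom", "start", "end", extra_cols)
  out <- df[, cols, drop = FALSE]
  for (j in seq_along(out)) if (is.numeric(out[[j]]))
    out[[j]] <- format(out[[j]], scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV (with header, no quoting)
#'
#' @param df data.frame to write.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
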