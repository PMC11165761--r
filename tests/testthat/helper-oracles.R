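# Independent brute-force / hand-formula oracles used to cross-check the
# package implementations. Deliberately written as plain loops over the
# definitions, sharing no code with the package internals.

bf_overlaps <- function(a, b) {
  # all-pairs scan over the cartesian product of the two sets
  g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  same <- sub("^chr", "", a$chrom[g$i]) == sub("^chr", "", b$chrom[g$j])
  ol <- pmin(a$end[g$i], b$end[g$j]) - pmax(a$start[g$i], b$start[g$j])
  keep <- same & ol >= 1
  res <- data.frame(index_a = g$i[keep], index_b = g$j[keep],
                    overlap_length = ol[keep])
  res[order(res$index_a, res$index_b), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1000) {
  start <- sample.int(span, n, replace = TRUE)
  w <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w,
             strand = "*", stringsAsFactors = FALSE)
}

# step-up BH by the textbook formula, independent of p.adjust
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, p[o] * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1)
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# hand product-limit table
bf_km <- function(times, events) {
  tt <- sort(unique(times[events > 0]))
  s <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in tt) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events > 0)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# standard O-E / V log-rank chi-square by direct summation
bf_logrank <- function(times, events, group) {
  g <- as.integer(factor(group))
  tt <- sort(unique(times[events > 0]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events > 0)
    d1 <- sum(times == t & events > 0 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# classic LOF by direct looped definition (k-distance ties included)
bf_lof <- function(x, y, k, standardize = TRUE) {
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
  pts <- if (standardize) cbind(zs(x), zs(y)) else cbind(x, y)
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  kdist <- numeric(n); nbrs <- vector("list", n)
  for (i in 1:n) {
    di <- d[i, -i]
    kdist[i] <- sort(di)[k]
    nbrs[[i]] <- setdiff(which(d[i, ] <= kdist[i]), i)
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in nbrs[[i]]) s <- s + max(kdist[j], d[i, j])
    lrd[i] <- if (s == 0) Inf else length(nbrs[[i]]) / s
  }
  lof <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in nbrs[[i]]) {
      r <- lrd[j] / lrd[i]
      s <- s + if (is.nan(r)) 1 else r
    }
    lof[i] <- s / length(nbrs[[i]])
  }
  lof
}

# single-linkage consolidation oracle: connected components of the
# pairwise-mergeable graph, found by breadth-first search
bf_consolidate <- function(calls, max_dist, require_type_match) {
  n <- nrow(calls)
  mate_chrom <- ifelse(is.na(calls$chrom2), calls$chrom1, calls$chrom2)
  mate_pos <- ifelse(is.na(calls$pos2), calls$pos1, calls$pos2)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- (!require_type_match || calls$sv_type[i] == calls$sv_type[j]) &&
      sub("^chr", "", calls$chrom1[i]) == sub("^chr", "", calls$chrom1[j]) &&
      sub("^chr", "", mate_chrom[i]) == sub("^chr", "", mate_chrom[j]) &&
      abs(calls$pos1[i] - calls$pos1[j]) <= max_dist &&
      abs(mate_pos[i] - mate_pos[j]) <= max_dist
    adj[i, j] <- ok
  }
  comp <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  reps <- lapply(split(seq_len(n), comp), function(idx) {
    g <- calls[idx, , drop = FALSE]
    o <- order(g$chrom1, g$pos1, ifelse(is.na(g$pos2), g$pos1, g$pos2), g$sv_id)
    r <- g[o[1], , drop = FALSE]
    r$support <- sum(g$support)
    r
  })
  res <- do.call(rbind, reps)
  res <- res[order(res$chrom1, res$pos1,
                   ifelse(is.na(res$pos2), res$pos1, res$pos2), res$sv_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

random_sv_calls <- function(n, sample_id = "S1", span = 20000) {
  types <- sample(c("DEL", "DUP", "INV", "TRA", "INS"), n, replace = TRUE)
  out <- list()
  for (i in seq_len(n)) {
    c1 <- sample(c("chr1", "chr2"), 1)
    if (types[i] == "TRA") {
      c2 <- setdiff(c("chr1", "chr2"), c1)
      p1 <- sample.int(span, 1); p2 <- sample.int(span, 1)
    } else if (types[i] == "INS") {
      c2 <- NA_character_
      p1 <- sample.int(span, 1); p2 <- NA_real_
    } else {
      c2 <- c1
      p1 <- sample.int(span, 1); p2 <- p1 + sample.int(span, 1)
    }
    out[[i]] <- data.frame(sv_id = sprintf("%s_r%03d", sample_id, i),
                           sample_id = sample_id, sv_type = types[i],
                           chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2,
                           quality = round(runif(1, 10, 60)), support = 1L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

small_cohort_config <- function(seed = 11)
  synthetic_config(n_noncaga = 24, n_caga = 8, n_genes = 50, n_planted = 5,
                   peaks_per_sample = 80, sv_per_sample = 8, seed = seed)
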