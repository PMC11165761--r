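test_that("candidate pairing respects the promoter distance bound", {
  gm <- data.frame(gene_id = "G1", symbol = "A", chrom = "chr1",
                   start = 1e6, end = 1.02e6, strand = "+", tss = 1e6)
  pk <- function(start, end) data.frame(chrom = "chr1", start = start,
                                        end = end, name = "pk")
  # 400 kb upstream of the TSS is in
  expect_equal(nrow(candidate_pairs(pk(6e5 - 1000, 6e5), gm)), 1L)
  # exactly 500,000 bp away is in, 500,001 is out
  expect_equal(nrow(candidate_pairs(pk(1e6 + 5e5, 1e6 + 5e5 + 100), gm)), 1L)
  expect_equal(nrow(candidate_pairs(pk(1e6 + 5e5 + 1, 1e6 + 5e5 + 100), gm)), 0L)
  # TSS inside the peak: distance zero
  expect_equal(candidate_pairs(pk(1e6 - 50, 1e6 + 50), gm)$distance_to_tss, 0)

  set.seed(2)
  for (rep in 1:20) {   # brute-force distance scan on random layouts
    gm <- data.frame(gene_id = sprintf("G%d", 1:10), symbol = sprintf("G%d", 1:10),
                     chrom = sample(c("chr1", "chr2"), 10, TRUE),
                     start = sample.int(3e6, 10), end = 0, strand = "+", tss = 0)
    gm$end <- gm$start + 1e4; gm$tss <- gm$start
    pks <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      start = sample.int(3e6, 15), end = 0,
                      name = sprintf("p%d", 1:15))
    pks$end <- pks$start + 1000
    got <- candidate_pairs(pks, gm, max_dist = 4e5)
    for (i in 1:15) for (g in 1:10) {
      d <- max(0, pks$start[i] - gm$tss[g], gm$tss[g] - (pks$end[i] - 1))
      expected <- pks$chrom[i] == gm$chrom[g] && d <= 4e5
      expect_equal(any(got$peak_id == pks$name[i] & got$gene_id == gm$gene_id[g]),
                   expected)
    }
  }
})

test_that("link correlation is Pearson with undefined cases dropped", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_link(x, x), 1)
  expect_equal(pearson_link(x, -2 * x + 7), -1)
  expect_true(is.na(pearson_link(x, rep(3, 5))))
  y <- c(2.2, 1.8, 3.9, 3.1, 5.4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_link(x, y), r_hand)
  # invariance under positive affine maps
  expect_equal(pearson_link(10 * x + 3, y), pearson_link(x, y))
  expect_error(pearson_link(c(1, 2), c(1, 2)))
})

test_that("permutation p-values have the add-one floor and two-sided symmetry", {
  x <- c(0.3, 1.2, 2.9, 3.1, 4.8, 5.5, 6.2, 7.9)
  p <- permutation_null_p(x, x, B = 999, seed = 1)
  expect_equal(p$p, 1 / 1000)             # attainable minimum
  expect_equal(p$r, 1)
  expect_length(p$null, 999)
  expect_true(all(abs(p$null) <= 1 + 1e-12))
  set.seed(4)
  y <- rnorm(8)
  expect_equal(permutation_null_p(x, y, B = 500, seed = 9)$p,
               permutation_null_p(x, -y, B = 500, seed = 9)$p)
  expect_error(permutation_null_p(x, y, B = 50), "at least 100")
})

test_that("permutation null equals a naive per-permutation correlation loop", {
  set.seed(6)
  x <- rnorm(12); y <- rnorm(12)
  set.seed(123); idx <- replicate(200, sample.int(12))
  got <- permutation_null_p(x, y, perm_idx = idx)
  naive <- vapply(seq_len(200), function(b) cor(x, y[idx[, b]]), 0)
  expect_equal(got$null, naive)
  expect_equal(got$p, (1 + sum(abs(naive) >= abs(cor(x, y)))) / 201)
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(10)
  for (rep in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bf_bh(p))
  }
})

test_that("least-squares fit recovers exact lines and matches normal equations", {
  pts_x <- c(0, 1, 2, 3); pts_y <- 2 * pts_x + 1
  fit <- least_squares_fit(pts_x, pts_y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  flat <- least_squares_fit(c(-2, -1, 1, 2), rep(5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 5)
  expect_error(least_squares_fit(rep(1, 4), 1:4), "constant")
  set.seed(14)
  for (rep in 1:50) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x))
    fit <- least_squares_fit(x, y)
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(fit$slope, b)
    expect_equal(fit$intercept, mean(y) - b * mean(x))
  }
})

test_that("LOF is near one in homogeneous density and flags the isolated point", {
  g <- expand.grid(x = 1:7, y = 1:7)
  lof <- lof_scores(g$x, g$y, k = 10, standardize = FALSE)
  interior <- g$x %in% 3:5 & g$y %in% 3:5
  expect_true(all(lof[interior] > 0.8 & lof[interior] < 1.2))

  set.seed(20)
  x <- c(rnorm(50, sd = 0.5), 15); y <- c(rnorm(50, sd = 0.5), 15)
  lof2 <- lof_scores(x, y, k = 10, standardize = FALSE)
  expect_equal(which.max(lof2), 51L)
  expect_gt(lof2[51], 1.5)

  expect_error(lof_scores(rnorm(10), rnorm(10), k = 10), "n >= k")
})

test_that("LOF matches the looped reference definition on random point sets", {
  set.seed(26)
  for (rep in 1:100) {
    n <- sample(12:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    k <- sample(3:10, 1)
    expect_equal(lof_scores(x, y, k = k), bf_lof(x, y, k),
                 tolerance = 1e-10)
  }
})

test_that("LOF agrees with the scikit-learn reference implementation", {
  set.seed(33)
  pts <- cbind(rnorm(60), rnorm(60))
  f_in <- tempfile(fileext = ".csv"); f_out <- tempfile(fileext = ".csv")
  write.table(pts, f_in, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- paste0(
    "import numpy as np\n",
    "from sklearn.neighbors import LocalOutlierFactor\n",
    "X = np.loadtxt('", f_in, "', delimiter=',')\n",
    "m = LocalOutlierFactor(n_neighbors=10)\n",
    "m.fit(X)\n",
    "np.savetxt('", f_out, "', -m.negative_outlier_factor_)\n")
  status <- system2("python", "-", input = code)
  expect_equal(status, 0L)
  ref <- scan(f_out, quiet = TRUE)
  expect_equal(lof_scores(pts[, 1], pts[, 2], k = 10, standardize = FALSE),
               ref, tolerance = 1e-6)
})

test_that("linking drops zero-variance links and the SE+SV filter ranks planted genes", {
  set.seed(41)
  n <- 40
  samples <- sprintf("S%02d", 1:n)
  sig <- matrix(rlnorm(3 * n), 3, n, dimnames = list(c("p1", "p2", "p3"), samples))
  expr <- matrix(rnorm(3 * n, 5), 3, n, dimnames = list(c("G1", "G2", "G3"), samples))
  # G1 driven by p1; G3 constant (dropped)
  sig["p1", 1:8] <- sig["p1", 1:8] * 10
  expr["G1", 1:8] <- expr["G1", 1:8] + 4
  expr["G3", ] <- 1
  pairs <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("G1", "G2", "G3"),
                      symbol = c("G1", "G2", "G3"), distance_to_tss = 0)
  expect_message(links <- link_pairs(pairs, sig, expr, B = 500, seed = 3),
                 "dropped")
  expect_equal(nrow(links), 2L)
  expect_true(all(links$fdr >= links$p))     # BH can only increase
  filt <- se_to_gene_filter(links, se_genes = c("G1", "G2"),
                            sv_genes = c("G1"), fdr_cut = 0.05)
  expect_equal(filt$gene_id, "G1")           # G2 lacks the SV annotation
  expect_true(filt$in_se & filt$has_sv)
  # fdr at/above the cut is excluded
  fake <- links; fake$fdr <- 0.06
  expect_equal(nrow(se_to_gene_filter(fake, "G1", "G1")), 0L)
})

test_that("SV-expression association classifies planted shifts and matches a t-test oracle", {
  set.seed(52)
  n <- 30
  samples <- sprintf("S%02d", 1:n)
  expr <- matrix(rnorm(20 * n, 5), 20, n,
                 dimnames = list(sprintf("G%02d", 1:20), samples))
  carriers <- do.call(rbind, lapply(1:20, function(g)
    data.frame(gene_id = sprintf("G%02d", g),
               sample_id = sample(samples, 6))))
  # plant +3 SD in the first 3 genes' carriers
  for (g in sprintf("G%02d", 1:3)) {
    car <- carriers$sample_id[carriers$gene_id == g]
    expr[g, car] <- expr[g, car] + 3
  }
  res <- sv_expression_association(expr, carriers)
  expect_true(all(res$status[1:3] == "elevated"))
  # oracle: per-gene equal-variance t-test + BH
  p_or <- vapply(1:20, function(i) {
    car <- carriers$sample_id[carriers$gene_id == rownames(expr)[i]]
    stats::t.test(expr[i, car], expr[i, setdiff(samples, car)],
                  var.equal = TRUE)$p.value
  }, 0)
  expect_equal(res$p, p_or)
  expect_equal(res$fdr, bf_bh(p_or))
  # identical distributions: nothing called
  null_res <- sv_expression_association(expr[4:20, ], carriers)
  expect_true(all(null_res$status == "unchanged"))
  # too few carriers: unchanged
  one <- sv_expression_association(expr,
    data.frame(gene_id = "G04", sample_id = samples[1]))
  expect_true(all(one$status == "unchanged"))
})
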