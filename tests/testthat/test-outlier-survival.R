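test_that("the IQR upper fence follows type-7 quartiles", {
  b <- iqr_upper_bound(1:8)
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)     # hand interpolation: x[6] + 0.25*(x[7]-x[6])
  expect_equal(b$iqr, 3.5)
  expect_equal(b$upper_bound, 11.5)
  const <- iqr_upper_bound(rep(3, 6))
  expect_equal(const$upper_bound, 3)
  expect_error(iqr_upper_bound(1:3), "at least 4")
})

test_that("the fence is affine-equivariant and outliers are sample-order invariant", {
  set.seed(61)
  for (rep in 1:50) {
    x <- rnorm(sample(8:60, 1))
    a <- runif(1, 0.1, 5); c <- runif(1, -10, 10)
    b0 <- iqr_upper_bound(x); b1 <- iqr_upper_bound(a * x + c)
    expect_equal(b1$upper_bound, a * b0$upper_bound + c)
    perm <- sample(seq_along(x))
    expect_equal(iqr_upper_bound(x[perm])$upper_bound, b0$upper_bound)
  }
})

test_that("expression outlier calls flag planted values and match a recount", {
  set.seed(62)
  n <- 40
  expr <- matrix(rnorm(5 * n, 5), 5, n,
                 dimnames = list(sprintf("G%d", 1:5), sprintf("S%02d", 1:n)))
  expr["G2", ] <- 7                               # constant: no outliers
  b <- iqr_upper_bound(expr["G1", -1])
  expr["G1", 1] <- b$q3 + 2 * b$iqr               # planted above the fence
  calls <- call_expression_outliers(expr, sprintf("G%d", 1:5))
  expect_true(calls$is_outlier[calls$gene_id == "G1" & calls$sample_id == "S01"])
  expect_false(any(calls$is_outlier[calls$gene_id == "G2"]))
  # brute-force recount
  for (g in rownames(expr)) {
    q <- quantile(expr[g, ], c(.25, .75), type = 7, names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    expect_equal(sum(calls$is_outlier[calls$gene_id == g]),
                 sum(expr[g, ] > fence))
  }
  expect_message(call_expression_outliers(expr, c("G1", "NOPE")), "missing")
})

test_that("case status is the union of per-gene outlier flags", {
  calls <- data.frame(gene_id = rep(c("A", "B"), each = 3),
                      sample_id = rep(c("S1", "S2", "S3"), 2),
                      value = 0, q1 = 0, q3 = 0, iqr = 0, upper_bound = 0,
                      is_outlier = c(TRUE, FALSE, FALSE,
                                     FALSE, FALSE, FALSE))
  st <- outlier_case_status(calls)
  expect_equal(unname(st[c("S1", "S2", "S3")]), c(TRUE, FALSE, FALSE))
  expect_length(outlier_case_status(calls[0, ]), 0L)
})

test_that("the product-limit curve matches hand computation and the empirical survival", {
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  cens <- km_estimate(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$surv == 1))
  # mixed small example, hand table: 2 events at t=2 (5 at risk), censor at
  # t=3, 1 event at t=4 (2 at risk), censor at t=6
  km2 <- km_estimate(c(2, 3, 4, 6, 2), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  hand <- bf_km(c(2, 3, 4, 6, 2), c(1, 0, 1, 0, 1))
  expect_equal(km2$surv[km2$n_event > 0], hand$surv)
  expect_equal(hand$surv, c(1 - 2/5, (1 - 2/5) * (1 - 1/2)))
  # no censoring: identical to the empirical survival function
  set.seed(63)
  for (rep in 1:50) {
    t <- round(rexp(sample(5:40, 1)), 2)
    km3 <- km_estimate(t, rep(TRUE, length(t)))
    ecdf_surv <- 1 - ecdf(t)(km3$time)
    expect_equal(km3$surv, ecdf_surv)
  }
})

test_that("the log-rank test matches the O-E/V hand computation", {
  t <- c(3, 5, 7, 2, 4, 6); e <- c(1, 1, 0, 1, 1, 1)
  g <- rep(c("a", "b"), each = 3)
  got <- logrank_test(t, e, g)
  hand <- bf_logrank(t, e, g)
  expect_equal(got$chi2, hand$chi2)
  expect_equal(got$p, hand$p)
  # identical groups: no signal
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1), g)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # label swap leaves the statistic unchanged
  swap <- logrank_test(t, e, rev(g))
  expect_equal(swap$chi2, got$chi2)
  expect_error(logrank_test(t, rep(0, 6), g), "no events")
  expect_error(logrank_test(t, e, rep("a", 6)), "two groups")
  set.seed(64)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    t <- round(rexp(n, 0.1), 3); e <- runif(n) < 0.7
    g <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    got <- logrank_test(t, e, g)
    hand <- bf_logrank(t, e, g)
    expect_equal(got$chi2, hand$chi2, tolerance = 1e-8)
  }
})

test_that("stratified RFS composes curves and test, and rejects empty strata", {
  set.seed(65)
  cl <- data.frame(sample_id = sprintf("S%03d", 1:100),
                   cohort = "non-CAGA",
                   rfs_time = round(rexp(100, 0.05), 2),
                   rfs_event = runif(100) < 0.8)
  status <- setNames(rep(c(TRUE, FALSE), 50), cl$sample_id)
  res <- stratified_rfs(cl, status)
  expect_equal(res$n_pos, 50)
  expect_equal(res$curve_pos$surv[1] <= 1, TRUE)
  expect_equal(res$p, logrank_test(cl$rfs_time, cl$rfs_event,
                                   cl$sample_id %in% names(status)[status])$p)
  expect_error(stratified_rfs(cl, setNames(rep(FALSE, 100), cl$sample_id)),
               "positive stratum")
  expect_error(stratified_rfs(cl, setNames(rep(TRUE, 100), cl$sample_id)),
               "negative stratum")
})

test_that("outlier prevalence is the fraction of positive cases per gene", {
  calls <- data.frame(gene_id = rep(c("A", "B", "C"), each = 4),
                      sample_id = rep(sprintf("S%d", 1:4), 3),
                      value = 0, q1 = 0, q3 = 0, iqr = 0, upper_bound = 0,
                      is_outlier = c(TRUE, TRUE, FALSE, FALSE,   # A
                                     TRUE, FALSE, TRUE, FALSE,   # B
                                     FALSE, FALSE, FALSE, FALSE))# C
  prev <- outlier_prevalence(calls)
  # positive cases: S1, S2, S3
  expect_equal(unname(prev[c("A", "B", "C")]), c(2/3, 2/3, 0))
  expect_true(all(prev >= 0 & prev <= 1))
  none <- calls; none$is_outlier <- FALSE
  expect_error(outlier_prevalence(none), "no outlier-positive")
  set.seed(66)
  for (rep in 1:30) {   # brute-force recount on random flag matrices
    m <- matrix(runif(60) < 0.2, 6, 10,
                dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
    calls <- data.frame(gene_id = rep(rownames(m), 10),
                        sample_id = rep(colnames(m), each = 6),
                        value = 0, q1 = 0, q3 = 0, iqr = 0, upper_bound = 0,
                        is_outlier = as.vector(m))
    if (!any(m)) next
    prev <- outlier_prevalence(calls)
    pos <- colnames(m)[colSums(m) > 0]
    for (g in rownames(m))
      expect_equal(unname(prev[g]), sum(m[g, pos]) / length(pos))
  }
})

test_that("named gene sets resolve from keyword, vector or file", {
  expect_equal(outlier_gene_set("top6"),
               c("CDK4", "ERBB2", "MDM2", "FRS2", "EGFR", "CAV2"))
  expect_equal(outlier_gene_set(c("A", "B")), c("A", "B"))
  f <- withr::local_tempfile()
  writeLines(c("FGF3", "FGF4", "", "FGF19"), f)
  expect_equal(outlier_gene_set(f), c("FGF3", "FGF4", "FGF19"))
})
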