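test_that("expression filtering keeps inclusive boundaries", {
  m <- matrix(c(0, 0, 0,
                1.0, 0, 0,
                0.99, 0.5, 0.2,
                5, 5, 5), 4, 3, byrow = TRUE,
              dimnames = list(c("zero", "boundary", "below", "high"),
                              c("s1", "s2", "s3")))
  f <- filter_expressed(m, min_fpkm = 1, min_samples = 1)
  expect_setequal(rownames(f), c("boundary", "high"))
  f2 <- filter_expressed(m, min_fpkm = 1, min_samples = 2)
  expect_setequal(rownames(f2), "high")
})

make_expr_fixture <- function(n_samp = 10, seed = 1) {
  set.seed(seed)
  genes <- c("flat", "outlier")
  m <- matrix(2^5, 2, n_samp,
              dimnames = list(genes, sprintf("s%02d", 1:n_samp)))
  st <- matrix(0L, 2, n_samp, dimnames = dimnames(m))
  list(mat = m, status = st)
}

test_that("identical diploid values classify everything normal", {
  fx <- make_expr_fixture()
  suppressWarnings(calls <- classify_expression(fx$mat, fx$status))
  expect_true(all(calls$level == "normal"))
})

test_that("extreme samples are flagged high against the diploid interval", {
  set.seed(2)
  n <- 10
  vals <- 2^rnorm(n, 5, 0.3)
  m <- rbind(g1 = vals)
  st <- rbind(g1 = c(rep(0L, n - 1), 1L))  # last sample amplified
  colnames(m) <- colnames(st) <- sprintf("s%02d", 1:n)
  s <- sd(log2(vals[1:(n - 1)] + 1))
  m["g1", n] <- 2^(log2(mean(vals[1:(n - 1)])) + 10 * s)
  calls <- classify_expression(m, st)
  expect_equal(calls$level[calls$sample_id == "s10"], "high")
  expect_true(all(calls$level[calls$sample_id != "s10"] == "normal"))
  expect_equal(unique(calls$n_diploid), n - 1)
})

test_that("genes with too few diploid references are unclassifiable", {
  m <- rbind(g1 = c(10, 20, 30, 40))
  st <- rbind(g1 = c(1L, 1L, 0L, 0L))
  colnames(m) <- colnames(st) <- paste0("s", 1:4)
  calls <- classify_expression(m, st, min_diploid = 3)
  expect_true(all(calls$level == "unclassifiable"))
})

test_that("held-out diploid draws are called normal at ~ 1 - alpha", {
  # prediction-interval coverage on a Gaussian null, 8 reference samples
  set.seed(33)
  n_rep <- 2000
  hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ref <- rnorm(8, 5, 0.7)
    iv <- diploid_interval(ref, alpha = 0.05)
    x <- rnorm(1, 5, 0.7)
    hit[r] <- x >= iv[1] && x <= iv[2]
  }
  expect_lt(abs(mean(hit) - 0.95), 0.02)
})

test_that("concordance columns sum to 100 and track coupling", {
  # drivers coupled to copy number at zero noise: Amp column all high
  g <- make_genome(n_chrom = 1, chrom_len = 2e6, gene_count = 30, seed = 3)
  sids <- sprintf("S%02d", 1:8)
  tr <- do.call(rbind, lapply(1:8, function(s) {
    if (s <= 2) data.frame(sample_id = sids[s], chrom = "chr1", start = 0,
                           end = 2e6, log2 = 1, class = "amp")
    else NULL
  }))
  A <- gene_true_log2(g, tr)
  A <- cbind(A, matrix(0, nrow(A), 6,
                       dimnames = list(rownames(A), sids[3:8])))
  e <- simulate_expression(g, A, driver_ids = rownames(A), sd = 0.05,
                           coupling = 1, seed = 4)
  st <- matrix(as.integer(A > 0), nrow(A), dimnames = dimnames(A))
  gc <- new_gene_cna(g$genes[match(rownames(A), g$genes$gene_id), ], st, A)
  calls <- classify_expression(e, gc)
  ct <- concordance_table(calls, gc)
  expect_equal(unname(colSums(ct)[colSums(attr(ct, "counts")) > 0]),
               rep(100, sum(colSums(attr(ct, "counts")) > 0)),
               tolerance = 1e-6)
  expect_equal(ct["high", "Amp"], 100)
  # no deletions anywhere: Del column empty
  expect_equal(sum(attr(ct, "counts")[, "Del"]), 0)
})

test_that("concordance with no CNAs populates only the unchanged column", {
  fx <- make_expr_fixture(seed = 5)
  set.seed(5)
  fx$mat <- matrix(2^rnorm(20, 5, 0.3), 2, 10, dimnames = dimnames(fx$mat))
  calls <- classify_expression(fx$mat, fx$status)
  ct <- concordance_table(calls, fx$status)
  expect_equal(sum(attr(ct, "counts")[, c("Del", "Amp")]), 0)
  expect_equal(unname(colSums(ct)["unchanged"]), 100)
})

test_that("Welch differential expression matches t.test and controls nulls", {
  set.seed(6)
  m <- matrix(2^rnorm(2000 * 8, 5, 1), 2000, 8,
              dimnames = list(sprintf("g%04d", 1:2000),
                              c(paste0("T", 1:4), paste0("N", 1:4))))
  tum <- paste0("T", 1:4); nor <- paste0("N", 1:4)
  de <- differential_expression_ttest(m, tum, nor, fdr = 0.1)
  # cross-check one gene against stats::t.test
  g <- "g0042"
  tt <- t.test(log2(m[g, tum] + 1), log2(m[g, nor] + 1))
  expect_equal(de$p[de$gene_id == g], tt$p.value)
  expect_equal(de$t[de$gene_id == g], unname(tt$statistic))
  # raw p uniform under the null; BH keeps false calls near zero
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  expect_lte(sum(de$significant), 2)

  # identical groups: nothing significant
  m2 <- m; m2[, nor] <- m2[, tum]
  de2 <- differential_expression_ttest(m2, tum, nor)
  expect_equal(sum(de2$significant), 0)

  # one strongly shifted gene is found
  m3 <- m; m3["g0001", tum] <- m3["g0001", tum] * 2^6
  de3 <- differential_expression_ttest(m3, tum, nor)
  expect_true(de3$significant[de3$gene_id == "g0001"])
  expect_equal(de3$direction[de3$gene_id == "g0001"], 1)
})

test_that("Hotelling T2 is zero for identical groups and reduces to t^2", {
  set.seed(7)
  A <- cbind(rnorm(20), rnorm(20))
  h <- hotelling_concordance(A, A)
  expect_equal(h$t2, 0, tolerance = 1e-10)
  expect_equal(h$p_value, 1)

  # one dimension: T2 equals the squared pooled-variance t statistic
  x <- matrix(rnorm(15, 1), ncol = 1)
  y <- matrix(rnorm(12), ncol = 1)
  h1 <- hotelling_concordance(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(h1$t2, unname(tt$statistic)^2)
  expect_equal(h1$p_value, tt$p.value)
})

test_that("coupled and uncoupled gene features separate by Hotelling", {
  # DCG-like genes: expression tracks copy number; PCG-like: flat
  set.seed(8)
  n <- 100
  cn_a <- rnorm(n, 0.8, 0.3)
  dcg <- cbind(cn = cn_a, expr = 5 + 1 * cn_a + rnorm(n, 0, 0.4))
  cn_b <- rnorm(n, 0.8, 0.3)
  pcg <- cbind(cn = cn_b, expr = 5 + rnorm(n, 0, 0.4))
  h <- hotelling_concordance(dcg, pcg)
  expect_lt(h$p_value, 0.05)
})

test_that("singular pooled covariance is a clear error", {
  A <- cbind(1:10, 1:10)  # perfectly collinear
  expect_error(hotelling_concordance(A, A + 1), "singular")
})
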