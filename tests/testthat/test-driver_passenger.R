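two_block_map <- function() {
  data.frame(human_chrom = "h1", h_start = c(0, 600), h_end = c(600, 1000),
             dog_chrom = c("dA", "dB"), d_start = c(100, 0),
             d_end = c(700, 400), orientation = c("+", "-"),
             stringsAsFactors = FALSE)
}

test_that("projection transfers plus blocks verbatim and reverses minus", {
  map <- two_block_map()
  pr <- project_region("h1", 0, 600, map, from = "human")
  expect_equal(pr$regions$chrom, "dA")
  expect_equal(pr$regions$start, 100)
  expect_equal(pr$regions$end, 700)
  expect_equal(nrow(pr$unmapped), 0)

  # minus block: human start maps to dog end
  p <- project_point("h1", 600, map, from = "human")
  expect_equal(p$chrom, "dB")
  expect_equal(p$pos, 399)
  p2 <- project_point("h1", 999, map, from = "human")
  expect_equal(p2$pos, 0)
})

test_that("unmapped gaps are reported, never dropped", {
  map <- two_block_map()[1, ]
  expect_warning(pr0 <- project_region("h1", 700, 900, map, from = "human"),
                 "unmapped")
  expect_equal(nrow(pr0$regions), 0)
  expect_equal(pr0$unmapped$start, 700)

  pr1 <- project_region("h1", 500, 800, map, from = "human")
  expect_equal(pr1$regions$src_end, 600)
  expect_equal(pr1$unmapped$start, 600)
  expect_equal(pr1$unmapped$end, 800)
})

test_that("projection preserves mapped length and round-trips", {
  set.seed(15)
  for (r in 1:20) {
    # random non-overlapping human blocks of random orientation
    n_blk <- sample(2:4, 1)
    bs <- sort(sample(seq(0, 9000, by = 500), n_blk))
    gap <- diff(c(bs, 9800))
    len <- pmax(10, floor(gap * runif(n_blk, 0.3, 0.9) / 10) * 10)
    map <- data.frame(human_chrom = "h1", h_start = bs, h_end = bs + len,
                      dog_chrom = paste0("d", seq_len(n_blk)),
                      d_start = 50, d_end = 50 + len,
                      orientation = sample(c("+", "-"), n_blk, TRUE),
                      stringsAsFactors = FALSE)
    q <- sort(sample(0:9500, 2)); if (q[2] == q[1]) q[2] <- q[1] + 1
    pr <- suppressWarnings(project_region("h1", q[1], q[2], map,
                                          from = "human"))
    mapped_len <- sum(pr$regions$end - pr$regions$start)
    unmapped_len <- sum(pr$unmapped$end - pr$unmapped$start)
    expect_equal(mapped_len + unmapped_len, q[2] - q[1])
    # each mapped piece round-trips to its source sub-interval
    for (i in seq_len(nrow(pr$regions))) {
      back <- project_region(pr$regions$chrom[i], pr$regions$start[i],
                             pr$regions$end[i], map, from = "dog")
      expect_equal(back$regions$start, pr$regions$src_start[i])
      expect_equal(back$regions$end, pr$regions$src_end[i])
    }
  }
})

make_recurrence <- function(n_amp_a, n_unch_a, n_amp_b, n_unch_b,
                            n_del_a = 0) {
  n_a <- n_amp_a + n_unch_a + n_del_a
  n_b <- n_amp_b + n_unch_b
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n_a + n_b)),
    chrom = c(rep("dA", n_a), rep("dB", n_b)),
    start = c(seq_len(n_a) * 10, seq_len(n_b) * 10),
    end = c(seq_len(n_a) * 10 + 5, seq_len(n_b) * 10 + 5),
    q_amp = c(rep(0.01, n_amp_a), rep(0.9, n_unch_a), rep(0.9, n_del_a),
              rep(0.01, n_amp_b), rep(0.9, n_unch_b)),
    q_del = c(rep(0.9, n_amp_a + n_unch_a), rep(0.01, n_del_a),
              rep(0.9, n_b)),
    stringsAsFactors = FALSE)
}

dp_regions <- function() {
  data.frame(chrom = c("dA", "dB"), start = 0, end = 1e5,
             stringsAsFactors = FALSE)
}

test_that("the worked two-region example discriminates decisively", {
  rec <- make_recurrence(125, 85, 2, 186)
  hg <- data.frame(gene_id = rec$gene_id, amplified = TRUE)
  res <- discriminate_drivers(rec, hg, dp_regions(), fdr = 0.2)
  expect_equal(unname(res$table[, 1]), c(125, 85))
  expect_equal(unname(res$table[, 2]), c(2, 186))
  expect_lt(res$p_value, 2.2e-16)
  expect_equal(res$status, "discriminated")
  expect_length(res$dcg_ids, 125)
  expect_length(res$pcg_ids, 186)
})

test_that("homogeneous regions yield no discrimination", {
  rec <- make_recurrence(50, 50, 50, 50)
  hg <- data.frame(gene_id = rec$gene_id, amplified = TRUE)
  res <- discriminate_drivers(rec, hg, dp_regions())
  expect_equal(res$p_value, 1)
  expect_equal(res$status, "no_discrimination")
  expect_length(res$dcg_ids, 0)
  expect_length(res$pcg_ids, 0)
})

test_that("discrimination Fisher p equals hypergeometric enumeration", {
  rec <- make_recurrence(3, 1, 1, 3)
  hg <- data.frame(gene_id = rec$gene_id, amplified = TRUE)
  res <- discriminate_drivers(rec, hg, dp_regions(), alpha = 0.5)
  tab <- matrix(c(3, 1, 1, 3), 2, 2)
  expect_equal(res$p_value, fisher_enum_p(tab), tolerance = 1e-9)
  expect_equal(res$p_value, 0.4857143, tolerance = 1e-6)
})

test_that("deleted genes are excluded from both candidate sets", {
  rec <- make_recurrence(40, 10, 1, 60, n_del_a = 5)
  hg <- data.frame(gene_id = rec$gene_id, amplified = TRUE)
  res <- discriminate_drivers(rec, hg, dp_regions())
  expect_length(res$deleted_ids, 5)
  expect_length(intersect(res$deleted_ids, c(res$dcg_ids, res$pcg_ids)), 0)
})

test_that("fewer than two regions is an explanatory error", {
  rec <- make_recurrence(10, 10, 0, 0)
  hg <- data.frame(gene_id = rec$gene_id, amplified = TRUE)
  expect_error(discriminate_drivers(rec, hg, dp_regions()[1, ]),
               "synteny break")
})

test_that("a non-amplified human region is rejected", {
  rec <- make_recurrence(5, 5, 5, 5)
  hg <- data.frame(gene_id = rec$gene_id,
                   amplified = c(FALSE, rep(TRUE, nrow(rec) - 1)))
  expect_error(discriminate_drivers(rec, hg, dp_regions()),
               "amplified")
})

test_that("mutation enrichment of DCGs over PCGs is exact", {
  # equal mutation rates: OR ~ 1
  eq <- validate_mutation_enrichment(paste0("d", 1:20), paste0("p", 1:20),
                                     c(paste0("d", 1:5), paste0("p", 1:5)))
  expect_equal(eq$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(eq$p_value, 1)

  # all DCGs mutated, no PCGs: closed-form hypergeometric extreme
  ex <- validate_mutation_enrichment(paste0("d", 1:5), paste0("p", 1:5),
                                     paste0("d", 1:5))
  expect_equal(ex$p_value, fisher_enum_p(matrix(c(5, 0, 0, 5), 2, 2)),
               tolerance = 1e-9)
  # the two equally extreme tables each carry 1/C(10,5)
  expect_equal(ex$p_value, 2 / choose(10, 5), tolerance = 1e-9)

  expect_error(validate_mutation_enrichment(c("a", "b"), c("b", "c"), "a"),
               "disjoint")
})

test_that("mutation-enrichment power grows with set size", {
  set.seed(16)
  power_at <- function(n_set) {
    hits <- 0
    for (r in 1:40) {
      mut_d <- rbinom(n_set, 1, 0.4) == 1
      mut_p <- rbinom(n_set, 1, 0.2) == 1
      dcg <- sprintf("d%03d", seq_len(n_set))
      pcg <- sprintf("p%03d", seq_len(n_set))
      v <- validate_mutation_enrichment(dcg, pcg,
                                        c(dcg[mut_d], pcg[mut_p]))
      if (v$p_value < 0.05) hits <- hits + 1
    }
    hits / 40
  }
  expect_gt(power_at(150), power_at(15))
  expect_gt(power_at(150), 0.8)
})

test_that("concordance validation separates coupled from uncoupled genes", {
  set.seed(17)
  n <- 60
  cn <- rnorm(2 * n, 0.8, 0.3)
  feats <- rbind(
    cbind(cn = cn[1:n], expr = 5 + cn[1:n] + rnorm(n, 0, 0.4)),
    cbind(cn = cn[(n + 1):(2 * n)], expr = 5 + rnorm(n, 0, 0.4)))
  rownames(feats) <- c(sprintf("d%03d", 1:n), sprintf("p%03d", 1:n))
  h <- validate_concordance(sprintf("d%03d", 1:n), sprintf("p%03d", 1:n),
                            feats)
  expect_lt(h$p_value, 0.05)
})
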