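test_that("probe density matches the requested mean spacing", {
  g <- make_genome(n_chrom = 1, chrom_len = 10e6, gene_count = 10,
                   probe_spacing = 5500, seed = 3)
  n <- nrow(g$probes)
  # 10 Mb at one probe per 5.5 kb on average: ~1818 probes
  expect_gt(n, 1700)
  expect_lt(n, 1950)
  expect_true(all(diff(g$probes$pos) > 0))
})

test_that("generators are deterministic under a fixed seed", {
  g1 <- make_genome(seed = 9); g2 <- make_genome(seed = 9)
  expect_identical(g1, g2)
  tr <- simulate_cna_truth(g1, c("A", "B"), seed = 4)
  expect_identical(tr, simulate_cna_truth(g2, c("A", "B"), seed = 4))
  p1 <- simulate_acgh(g1, tr, seed = 5)
  expect_identical(p1, simulate_acgh(g1, tr, seed = 5))
  ref <- make_reference(c(c1 = 2e4), seed = 6)
  expect_identical(ref, make_reference(c(c1 = 2e4), seed = 6))
  v1 <- simulate_variants(ref, spectrum_profile(), 200, seed = 7)
  expect_identical(v1, simulate_variants(ref, spectrum_profile(), 200,
                                         seed = 7))
})

test_that("gene placement respects counts and chromosome bounds", {
  g <- make_genome(n_chrom = 2, chrom_len = 1e6, gene_count = 10,
                   probe_spacing = 5000, seed = 2)
  expect_equal(nrow(g$genes), 20)
  len <- g$chromosomes$length[match(g$genes$chrom, g$chromosomes$chrom)]
  expect_true(all(g$genes$start >= 0 & g$genes$end <= len))
  # non-overlap within chromosome
  for (ch in unique(g$genes$chrom)) {
    d <- g$genes[g$genes$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_error(make_genome(n_chrom = 1, chrom_len = 1000, gene_count = 2000,
                           probe_spacing = 100, seed = 1),
               "cannot pack")
})

test_that("zero-noise aCGH reproduces truth amplitudes exactly", {
  g <- make_genome(n_chrom = 1, chrom_len = 1e6, gene_count = 5, seed = 1)
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = 2e5,
                   end = 4e5, log2 = 1.0, class = "amp")
  pr <- simulate_acgh(g, tr, noise_sd = 0, seed = 1)
  inside <- pr$pos >= 2e5 & pr$pos < 4e5
  expect_true(all(pr$S1[inside] == 1.0))
  expect_true(all(pr$S1[!inside] == 0.0))
})

test_that("null aCGH profiles average to zero within Monte-Carlo bounds", {
  g <- make_genome(n_chrom = 1, chrom_len = 2e6, gene_count = 5, seed = 1)
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = 0, end = 1,
                   log2 = 0, class = "amp")
  pr <- simulate_acgh(g, tr, noise_sd = 0.2, seed = 8)
  n <- nrow(pr)
  expect_lt(abs(mean(pr$S1)), 4 * 0.2 / sqrt(n))
})

test_that("truth segments outside the genome are rejected", {
  g <- make_genome(n_chrom = 1, chrom_len = 1e6, gene_count = 5, seed = 1)
  bad <- data.frame(sample_id = "S1", chrom = "chr1", start = 5e5,
                    end = 2e6, log2 = 1, class = "amp")
  expect_error(simulate_acgh(g, bad), "outside")
  bad2 <- data.frame(sample_id = "S1", chrom = "chr9", start = 0,
                     end = 10, log2 = 1, class = "amp")
  expect_error(simulate_acgh(g, bad2), "absent")
})

test_that("a focal amplicon can cover a fixed number of genes end to end", {
  # emulates a ~10 Mb focal amplification harboring 63 genes
  g <- make_genome(n_chrom = 1, chrom_len = 12e6, gene_count = 76,
                   seed = 21)
  ord <- g$genes[order(g$genes$start), ]
  sel <- ord[6:68, ]  # 63 consecutive genes
  tr <- data.frame(sample_id = "S1", chrom = "chr1",
                   start = min(sel$start) - 100,
                   end = max(sel$end) + 100, log2 = 1, class = "amp")
  mid <- (sel$start + sel$end) / 2
  expect_equal(nrow(sel), 63)
  expect_true(all(mid >= tr$start & mid < tr$end))
  A <- gene_true_log2(g, tr)
  expect_equal(sum(A[, "S1"] == 1), 63)
})

test_that("expression coupling behaves as specified in the limits", {
  g <- make_genome(n_chrom = 1, chrom_len = 2e6, gene_count = 50, seed = 2)
  tr <- data.frame(sample_id = paste0("S", 1:20), chrom = "chr1",
                   start = 0, end = 1e6, log2 = rep(c(1, 0), 10),
                   class = "amp")
  A <- gene_true_log2(g, tr)
  # coupling 0: expression independent of copy status
  e0 <- simulate_expression(g, A, driver_ids = rownames(A),
                            coupling = 0, sd = 0.5, seed = 3)
  amp_gene <- rownames(A)[which(rowSums(A) > 0)[1]]
  expect_lt(abs(cor(A[amp_gene, ], log2(e0[amp_gene, ]))), 0.5)
  # coupling 1, sd -> 0: doubling copy number doubles expression
  e1 <- simulate_expression(g, A, driver_ids = rownames(A),
                            coupling = 1, sd = 0, seed = 3)
  expect_equal(unname(e1[amp_gene, A[amp_gene, ] == 1] /
                        e1[amp_gene, A[amp_gene, ] == 0][1]),
               rep(2, sum(A[amp_gene, ] == 1)))
  expect_error(simulate_expression(g, A, driver_ids = "nope"), "unknown")
})

test_that("driver-gene expression shift is recovered by Monte Carlo", {
  g <- make_genome(n_chrom = 1, chrom_len = 2e6, gene_count = 10, seed = 2)
  n_samp <- 100
  tr <- do.call(rbind, lapply(seq_len(n_samp), function(s) {
    data.frame(sample_id = sprintf("S%03d", s), chrom = "chr1",
               start = 0, end = if (s <= 50) 2e6 else 1,
               log2 = if (s <= 50) 1 else 0, class = "amp")
  }))
  A <- gene_true_log2(g, tr)
  gid <- rownames(A)[1]
  e <- simulate_expression(g, A, driver_ids = gid, sd = 0.5, coupling = 1,
                           seed = 4)
  shift <- mean(log2(e[gid, A[gid, ] == 1])) -
    mean(log2(e[gid, A[gid, ] == 0]))
  se <- 0.5 * sqrt(1 / 50 + 1 / 50)
  expect_lt(abs(shift - 1), 4 * se)
})

test_that("simulated variants follow the spectrum profile", {
  ref <- make_reference(c(chr1 = 1e5), seed = 5)
  # a pure C>T profile emits only C>T / G>A on the forward strand
  pure <- spectrum_profile(probs = c("C>A" = 0, "C>G" = 0, "C>T" = 1,
                                     "T>A" = 0, "T>C" = 0, "T>G" = 0))
  v <- simulate_variants(ref, pure, 500, seed = 6)
  expect_true(all(paste0(v$ref, ">", v$alt) %in% c("C>T", "G>A")))

  # multinomial convergence at 3 sigma for a skewed profile
  probs <- c("C>A" = 0.5, "C>G" = 0.1, "C>T" = 0.1, "T>A" = 0.1,
             "T>C" = 0.1, "T>G" = 0.1)
  v2 <- simulate_variants(ref, spectrum_profile(probs = probs), 10000,
                          seed = 7)
  cls <- collapse_class(v2$ref, v2$alt)$class
  obs <- table(factor(cls, levels = names(probs))) / length(cls)
  tol <- 3 * sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(as.numeric(obs) - probs) <= tol))
})

test_that("coverage filter is exercised by out-of-range depths", {
  ref <- make_reference(c(chr1 = 5e4), seed = 5)
  v <- simulate_variants(ref, spectrum_profile(), 4000,
                         coverage_range = c(30, 300),
                         out_of_range_rate = 0.1, seed = 8)
  kept <- filter_by_coverage(v, 30, 300)
  frac <- nrow(kept) / nrow(v)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.1 * 0.9 / 4000))
})

test_that("CpG transversion enrichment is detectable downstream with power", {
  ref <- make_reference(c(chr1 = 2e5), gc = 0.5, seed = 9)
  base <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.50, "T>A" = 0.06,
            "T>C" = 0.20, "T>G" = 0.06)
  p_pos <- spectrum_profile(probs = base, cpg_tv_multiplier = 3,
                            virus_status = "positive")
  p_neg <- spectrum_profile(probs = base, virus_status = "negative")
  n_rep <- 25
  hits <- 0
  for (r in seq_len(n_rep)) {
    vp <- simulate_variants(ref, p_pos, 2000, sample_id = "pos",
                            seed = 100 + r)
    vn <- simulate_variants(ref, p_neg, 2000, sample_id = "neg",
                            seed = 200 + r)
    cmp <- compare_cpg_transversions(vp, vn)
    if (cmp$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("synteny scenario reproduces the two-region gene split", {
  sc <- make_synteny_scenario(seed = 31)
  expect_equal(unname(sc$region_split), c(210, 188))
  expect_equal(sum(sc$region_split), 398)
  expect_equal(length(sc$driver_ids), 125)
  expect_true(all(sc$human_genes$amplified))
  # drivers live in region A (dchr13)
  drv <- sc$dog_genome$genes[sc$dog_genome$genes$gene_id %in% sc$driver_ids, ]
  expect_true(all(drv$chrom == "dchr13"))
})

test_that("driver_fraction = 0 gives a CNA-free region A", {
  sc <- make_synteny_scenario(driver_fraction = 0, background_rate = 0,
                              seed = 32)
  expect_length(sc$driver_ids, 0)
  expect_equal(nrow(sc$truth), 0)
})

test_that("projecting a dog region back recovers the human sub-interval", {
  sc <- make_synteny_scenario(seed = 33)
  fwd <- project_region("hchr8", 1e6, 5e6, sc$synteny, from = "human")
  expect_equal(nrow(fwd$regions), 1)
  back <- project_region(fwd$regions$chrom[1], fwd$regions$start[1],
                         fwd$regions$end[1], sc$synteny, from = "dog")
  expect_equal(back$regions$start[1], 1e6)
  expect_equal(back$regions$end[1], 5e6)
})
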