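# Shared fixture builders; everything is generated in code under fixed seeds.

# Small genome + implanted CNAs + probe table, one call.
tiny_cohort <- function(n_chrom = 2, chrom_len = 2e6, gene_count = 20,
                        sample_ids = c("S1", "S2"), probe_fraction = 0.1,
                        noise_sd = 0.2, seed = 1) {
  g <- make_genome(n_chrom = n_chrom, chrom_len = chrom_len,
                   gene_count = gene_count, seed = seed)
  tr <- simulate_cna_truth(g, sample_ids, probe_fraction = probe_fraction,
                           seed = seed + 1)
  pr <- simulate_acgh(g, tr, noise_sd = noise_sd, seed = seed + 2,
                      sample_ids = sample_ids)
  list(genome = g, truth = tr, probes = pr)
}

# Variant records with chosen CpG-site transition/transversion counts.
cpg_records <- function(n_tv, n_ti, sample_id = "S") {
  n <- n_tv + n_ti
  if (n == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), five_prime = character(),
                      three_prime = character(), stringsAsFactors = FALSE))
  }
  data.frame(sample_id = sample_id, chrom = "chr1", pos = seq_len(n) * 10L,
             ref = "C",
             alt = c(rep("A", n_tv), rep("T", n_ti)),
             depth = 100L, five_prime = "A", three_prime = "G",
             stringsAsFactors = FALSE)
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more likely than
# the observed one.  Independent of fisher.test.
fisher_enum_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- tab[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[x - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Reverse-complement a variant record table (strand flip of every field).
revcomp_records <- function(records) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  data.frame(sample_id = records$sample_id, chrom = records$chrom,
             pos = records$pos,
             ref = unname(comp[records$ref]),
             alt = unname(comp[records$alt]),
             depth = records$depth,
             five_prime = unname(comp[records$three_prime]),
             three_prime = unname(comp[records$five_prime]),
             stringsAsFactors = FALSE)
}
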