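# Synthetic-data generators.
#
# Every downstream stage of the pipeline is exercised on data produced here,
# with known ground truth: a genome model with probes and genes, implanted
# copy-number segments, copy-coupled expression for driver genes, substitution
# calls drawn from a configurable spectrum, and a two-genome synteny scenario
# in which one "human" amplicon is split across two "dog" regions.

#' Build a synthetic genome model with probes and genes
#'
#' Chromosomes are laid out with aCGH probes on a jittered grid (uniform
#' jitter of +/-40% around the nominal spacing, so the mean inter-probe
#' distance matches `probe_spacing` without grid artifacts) and
#' non-overlapping genes placed approximately uniformly.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (scalar, or vector of length
#'   `n_chrom`).
#' @param gene_count Number of genes *per chromosome*.
#' @param probe_spacing Mean inter-probe distance in bp.  The default mirrors
#'   a 385K oligo array design with roughly one probe every 5--6 kb.
#' @param gene_len Nominal gene length in bp; shrunk automatically when the
#'   requested gene count would not otherwise fit.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An object of class `genome_model`: a list with data frames
#'   `chromosomes` (chrom, length), `probes` (chrom, pos) and `genes`
#'   (gene_id, chrom, start, end, strand).  Gene intervals are 0-based
#'   half-open.
#' @export
make_genome <- function(n_chrom = 5, chrom_len = 10e6, gene_count = 100,
                        probe_spacing = 5500, gene_len = 20000, seed = 1) {
  stopifnot(n_chrom >= 1, all(chrom_len >= 1), gene_count >= 1,
            probe_spacing >= 1)
  chrom_len <- rep_len(chrom_len, n_chrom)
  if (any(probe_spacing >= chrom_len)) {
    stop("probe_spacing must be smaller than every chromosome length")
  }
  set.seed(seed)
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = chrom_len, stringsAsFactors = FALSE)

  probes <- list(); genes <- list()
  for (ci in seq_len(n_chrom)) {
    len <- chrom_len[ci]
    # jittered grid: gaps uniform in [0.6, 1.4] * spacing => mean = spacing
    n_gap <- ceiling(len / (0.6 * probe_spacing)) + 1
    gaps <- runif(n_gap, 0.6, 1.4) * probe_spacing
    pos <- floor(cumsum(gaps))
    pos <- pos[pos < len]
    pos <- unique(pos)                      # floors could collide
    probes[[ci]] <- data.frame(chrom = chroms$chrom[ci], pos = pos,
                               stringsAsFactors = FALSE)

    # one gene per equal-width slot keeps genes non-overlapping and ~uniform
    slot <- len / gene_count
    glen <- min(gene_len, floor(slot * 0.8))
    if (glen < 1) {
      stop(sprintf("cannot pack %d genes of length >= 1 bp into %d bp",
                   gene_count, len))
    }
    start <- floor((seq_len(gene_count) - 1) * slot +
                     runif(gene_count, 0, slot - glen))
    genes[[ci]] <- data.frame(
      gene_id = sprintf("g%d_%03d", ci, seq_len(gene_count)),
      chrom = chroms$chrom[ci],
      start = start, end = start + glen,
      strand = sample(c("+", "-"), gene_count, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- list(chromosomes = chroms,
              probes = do.call(rbind, probes),
              genes = do.call(rbind, genes))
  rownames(out$probes) <- rownames(out$genes) <- NULL
  class(out) <- "genome_model"
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d probes, %d genes\n",
              nrow(x$chromosomes), nrow(x$probes), nrow(x$genes)))
  invisible(x)
}

#' Implant ground-truth copy-number segments
#'
#' Places non-overlapping amplification/deletion segments per sample so that
#' approximately `probe_fraction` of the genome (by length, hence by probes)
#' lies inside a segment.  Amplitudes are drawn uniformly from `amp_range`
#' with a random sign.
#'
#' @param genome A [make_genome()] model.
#' @param sample_ids Character vector of sample names.
#' @param probe_fraction Fraction of the genome to cover with true CNAs.
#' @param segs_per_chrom Number of implanted segments per chromosome.
#' @param amp_range Absolute log2-amplitude range, e.g. `c(0.6, 1.5)`.
#' @param seed Integer seed.
#' @return A `data.frame` (class `cna_truth`) with columns sample_id, chrom,
#'   start, end, log2, class (`"amp"`/`"del"`); 0-based half-open.
#' @export
simulate_cna_truth <- function(genome, sample_ids = "S1",
                               probe_fraction = 0.05, segs_per_chrom = 1,
                               amp_range = c(0.6, 1.5), seed = 1) {
  stopifnot(inherits(genome, "genome_model"),
            probe_fraction >= 0, probe_fraction < 1,
            segs_per_chrom >= 1, amp_range[1] > 0)
  set.seed(seed)
  out <- list()
  for (sid in sample_ids) {
    for (ci in seq_len(nrow(genome$chromosomes))) {
      len <- genome$chromosomes$length[ci]
      seg_len <- floor(len * probe_fraction / segs_per_chrom)
      if (seg_len < 1) next
      # carve the chromosome into segs_per_chrom bins; one segment per bin
      bin <- floor(len / segs_per_chrom)
      for (si in seq_len(segs_per_chrom)) {
        start <- (si - 1) * bin + floor(runif(1, 0, bin - seg_len))
        amp <- runif(1, amp_range[1], amp_range[2]) *
          sample(c(-1, 1), 1)
        out[[length(out) + 1]] <- data.frame(
          sample_id = sid, chrom = genome$chromosomes$chrom[ci],
          start = start, end = start + seg_len, log2 = amp,
          class = if (amp > 0) "amp" else "del",
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), log2 = numeric(),
               class = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  class(truth) <- c("cna_truth", "data.frame")
  truth
}

validate_truth <- function(truth, genome) {
  stopifnot_cols(truth, c("sample_id", "chrom", "start", "end", "log2"),
                 "CNA truth")
  key <- chrom_key(truth$chrom)
  gkey <- chrom_key(genome$chromosomes$chrom)
  if (!all(key %in% gkey)) {
    stop("truth segment on a chromosome absent from the genome model")
  }
  len <- genome$chromosomes$length[match(key, gkey)]
  if (any(truth$start < 0) || any(truth$end > len)) {
    stop("truth segment outside chromosome bounds")
  }
  # non-overlap within sample/chromosome
  sp <- split(truth, paste(truth$sample_id, key))
  for (d in sp) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping truth segments within one sample")
    }
  }
  invisible(truth)
}

#' Simulate probe-level aCGH log2-ratio profiles
#'
#' Each probe takes the true log2 amplitude of the truth segment covering it
#' (0 outside any segment) plus Gaussian noise.
#'
#' @param genome A [make_genome()] model.
#' @param truth A [simulate_cna_truth()] table (possibly many samples).
#' @param noise_sd Gaussian probe noise, log2 units.
#' @param seed Integer seed.
#' @param sample_ids Samples to emit; defaults to those present in `truth`.
#'   Samples without truth segments get pure-noise (CNA-free) profiles.
#' @return A `data.frame` in the probe-table layout: columns `chrom`, `pos`,
#'   then one numeric column per sample.
#' @export
simulate_acgh <- function(genome, truth, noise_sd = 0.2, seed = 1,
                          sample_ids = unique(truth$sample_id)) {
  stopifnot(inherits(genome, "genome_model"), noise_sd >= 0)
  validate_truth(truth, genome)
  set.seed(seed)
  probes <- genome$probes
  out <- probes
  for (sid in sample_ids) {
    mu <- numeric(nrow(probes))
    tt <- truth[truth$sample_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(tt))) {
      hit <- chrom_key(probes$chrom) == chrom_key(tt$chrom[i]) &
        probes$pos >= tt$start[i] & probes$pos < tt$end[i]
      mu[hit] <- tt$log2[i]
    }
    out[[sid]] <- mu + rnorm(nrow(probes), 0, noise_sd)
  }
  out
}

#' True gene-level log2 copy amplitudes from a truth table
#'
#' A gene takes the amplitude of the truth segment containing its midpoint
#' (0 otherwise).
#'
#' @inheritParams simulate_acgh
#' @return Numeric matrix genes x samples of true log2 amplitudes.
#' @export
gene_true_log2 <- function(genome, truth) {
  validate_truth(truth, genome)
  genes <- genome$genes
  mid <- (genes$start + genes$end) / 2
  sids <- unique(truth$sample_id)
  A <- matrix(0, nrow(genes), length(sids),
              dimnames = list(genes$gene_id, sids))
  for (sid in sids) {
    tt <- truth[truth$sample_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(tt))) {
      hit <- chrom_key(genes$chrom) == chrom_key(tt$chrom[i]) &
        mid >= tt$start[i] & mid < tt$end[i]
      A[hit, sid] <- tt$log2[i]
    }
  }
  A
}

#' Simulate an expression matrix coupled to copy number for driver genes
#'
#' Log2 expression is `base_log2_mean + coupling * true_log2 + N(0, sd)` for
#' genes in `driver_ids`; the coupling term is omitted for all other
#' (passenger-like) genes, whose expression is independent of copy number.
#' Values are returned on the FPKM scale (`2^log2`).
#'
#' @param genome A [make_genome()] model.
#' @param true_log2 Matrix genes x samples of true log2 copy amplitudes
#'   (see [gene_true_log2()]).
#' @param driver_ids Gene ids whose expression tracks copy number.
#' @param base_log2_mean Baseline log2 expression.
#' @param sd Gaussian noise on the log2 scale.
#' @param coupling Multiplier converting copy log2 into expression log2
#'   (1 = dosage: doubling DNA doubles mRNA).
#' @param seed Integer seed.
#' @return Numeric matrix genes x samples, FPKM scale.
#' @export
simulate_expression <- function(genome, true_log2, driver_ids = character(),
                                base_log2_mean = 5, sd = 0.5, coupling = 1,
                                seed = 1) {
  stopifnot(inherits(genome, "genome_model"), coupling >= 0, sd >= 0)
  unknown <- setdiff(driver_ids, genome$genes$gene_id)
  if (length(unknown)) {
    stop("unknown gene id(s) in driver_ids: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  genes <- rownames(true_log2)
  stopifnot(all(genes %in% genome$genes$gene_id))
  set.seed(seed)
  eff <- true_log2 * coupling
  eff[!(genes %in% driver_ids), ] <- 0
  lg <- base_log2_mean + eff +
    matrix(rnorm(length(true_log2), 0, sd), nrow(true_log2))
  fpkm <- 2^lg
  dimnames(fpkm) <- dimnames(true_log2)
  fpkm
}

#' Construct a substitution-spectrum profile
#'
#' Probabilities over the six strand-collapsed substitution classes, plus
#' context multipliers.  The default spectrum is transition-dominated
#' (C>T/G>A is the largest class), the pattern typical of squamous tumors.
#'
#' @param probs Named numeric of length 6 over
#'   `c("C>A","C>G","C>T","T>A","T>C","T>G")`, summing to 1.
#' @param cpg_tv_multiplier Odds multiplier applied to the transversion
#'   classes (`C>A`, `C>G`) at CpG sites.
#' @param tpc_multiplier Odds multiplier applied to all C-classes at TpC
#'   sites (APOBEC-like enrichment).
#' @param virus_status `"positive"`, `"negative"` or `"unknown"`.
#' @return An object of class `spectrum_profile`.
#' @export
spectrum_profile <- function(probs = c("C>A" = 0.08, "C>G" = 0.06,
                                       "C>T" = 0.55, "T>A" = 0.05,
                                       "T>C" = 0.20, "T>G" = 0.06),
                             cpg_tv_multiplier = 1, tpc_multiplier = 1,
                             virus_status = "negative") {
  cls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  stopifnot(setequal(names(probs), cls),
            abs(sum(probs) - 1) < 1e-8,
            all(probs >= 0),
            cpg_tv_multiplier > 0, tpc_multiplier > 0)
  virus_status <- match.arg(virus_status, c("positive", "negative", "unknown"))
  structure(list(probs = probs[cls],
                 cpg_tv_multiplier = cpg_tv_multiplier,
                 tpc_multiplier = tpc_multiplier,
                 virus_status = virus_status),
            class = "spectrum_profile")
}

#' Generate a random reference sequence set
#'
#' @param chrom_len Named numeric vector of chromosome lengths (names become
#'   sequence names).
#' @param gc Overall G+C fraction.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
make_reference <- function(chrom_len = c(chr1 = 1e5), gc = 0.4, seed = 1) {
  stopifnot(all(chrom_len >= 3), gc > 0, gc < 1, !is.null(names(chrom_len)))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_len, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate substitution calls from a spectrum profile
#'
#' Sites are drawn uniformly from the reference; each variant's
#' strand-collapsed class is drawn from the profile, with transversion odds
#' multiplied by `cpg_tv_multiplier` at CpG sites.  Read depth is uniform in
#' `coverage_range`, except a fixed fraction of records deliberately outside
#' the range so that the coverage filter is always exercised.
#'
#' @param reference A [Biostrings::DNAStringSet] of reference sequences.
#' @param profile A [spectrum_profile()].
#' @param n_variants Number of substitutions to emit.
#' @param sample_id Sample name attached to every record.
#' @param coverage_range `c(min, max)` read depth.
#' @param out_of_range_rate Fraction of records with depth outside the range.
#' @param seed Integer seed.
#' @return A variant `data.frame`: sample_id, chrom, pos (0-based), ref, alt,
#'   depth, five_prime, three_prime.
#' @export
simulate_variants <- function(reference, profile, n_variants,
                              sample_id = "S1",
                              coverage_range = c(30, 300),
                              out_of_range_rate = 0.1, seed = 1) {
  stopifnot(inherits(profile, "spectrum_profile"), n_variants >= 0,
            coverage_range[1] <= coverage_range[2])
  set.seed(seed)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), five_prime = character(),
                      three_prime = character(), stringsAsFactors = FALSE)
  if (n_variants == 0) return(empty)

  chroms <- names(reference)
  seq_chr <- vapply(chroms, function(nm) as.character(reference[[nm]]),
                    character(1))
  # interior positions by strand-collapsed reference type (1-based here)
  cand <- lapply(seq_chr, function(s) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    idx <- 2:(n - 1)
    list(C = idx[b[idx] %in% c("C", "G")],
         T = idx[b[idx] %in% c("A", "T")],
         bases = b)
  })
  pc <- sum(profile$probs[c("C>A", "C>G", "C>T")])
  wlen <- vapply(chroms, function(nm) nchar(seq_chr[[nm]]), numeric(1))

  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n <- n_variants
  chrom_i <- sample(seq_along(chroms), n, replace = TRUE, prob = wlen)
  type <- ifelse(runif(n) < pc, "C", "T")
  pos1 <- integer(n); refb <- character(n)
  fiveb <- character(n); threeb <- character(n)
  for (i in seq_len(n)) {
    pool <- cand[[chrom_i[i]]][[type[i]]]
    if (!length(pool)) stop("reference has no sites of required base type")
    p1 <- pool[sample.int(length(pool), 1)]
    b <- cand[[chrom_i[i]]]$bases
    pos1[i] <- p1; refb[i] <- b[p1]
    fiveb[i] <- b[p1 - 1]; threeb[i] <- b[p1 + 1]
  }
  # strand-collapsed context flags at the sampled sites
  is_cpg <- (refb == "C" & threeb == "G") | (refb == "G" & fiveb == "C")
  is_tpc <- (refb == "C" & fiveb == "T") | (refb == "G" & threeb == "A")

  cls6 <- names(profile$probs)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (type[i] == "C") {
      w <- profile$probs[c("C>A", "C>G", "C>T")]
      if (is_cpg[i]) w[c("C>A", "C>G")] <- w[c("C>A", "C>G")] *
          profile$cpg_tv_multiplier
      if (is_tpc[i]) w <- w * profile$tpc_multiplier
    } else {
      w <- profile$probs[c("T>A", "T>C", "T>G")]
    }
    if (sum(w) <= 0) stop("spectrum profile assigns zero mass to a drawn type")
    cls[i] <- sample(names(w), 1, prob = w / sum(w))
  }
  alt_collapsed <- substr(cls, 3, 3)
  # if the genomic reference base is a purine, emit the reverse-strand pair
  on_reverse <- refb %in% c("A", "G")
  alt <- ifelse(on_reverse, comp[alt_collapsed], alt_collapsed)

  depth <- round(runif(n, coverage_range[1], coverage_range[2]))
  oo <- runif(n) < out_of_range_rate
  lo <- runif(sum(oo)) < 0.5
  depth[oo][lo] <- pmax(0L, round(runif(sum(lo), 0, coverage_range[1] - 1)))
  depth[oo][!lo] <- round(runif(sum(!lo), coverage_range[2] + 1,
                                coverage_range[2] * 2))

  data.frame(sample_id = sample_id, chrom = chroms[chrom_i],
             pos = pos1 - 1L, ref = refb, alt = unname(alt),
             depth = as.integer(depth), five_prime = fiveb,
             three_prime = threeb, stringsAsFactors = FALSE)
}

#' Build a two-genome synteny scenario with known drivers and passengers
#'
#' Emulates the situation in which one recurrently amplified "human" region
#' is split by interspecies rearrangement into two "dog" chromosomal regions:
#' all human genes in the region are amplified, while in the dog only region
#' A (carrying the implanted drivers) is recurrently amplified, and region B
#' (the passengers) is copy-neutral apart from random background CNAs.  The
#' default sizes mirror a ~66 Mb arm split into a 210-gene and a 188-gene
#' region with 398 genes total.
#'
#' @param human_region_len Length of the human region, bp.
#' @param n_genes Total genes in the region, placed on an even grid.
#' @param split_fraction Fraction of the region mapping to dog region A.
#' @param driver_fraction Fraction of region-A genes that are true drivers
#'   (implanted as a contiguous amplified run).
#' @param n_samples Number of simulated dog tumors.
#' @param amp_log2 True log2 amplitude of the driver amplification.
#' @param recurrence_rate Fraction of samples carrying the driver amplicon.
#' @param background_rate Per-sample expected count of random background
#'   segments elsewhere in the dog genome.
#' @param probe_spacing Mean aCGH probe spacing for the dog genome, bp.
#' @param seed Integer seed.
#' @return A list with elements `synteny` (block table), `human_genes`
#'   (all flagged amplified), `dog_genome` (a `genome_model` whose genes are
#'   the projected orthologs), `driver_ids`, `truth` (dog `cna_truth`) and
#'   `region_split` (gene counts per dog region).
#' @export
make_synteny_scenario <- function(human_region_len = 66e6, n_genes = 398,
                                  split_fraction = 210 / 398,
                                  driver_fraction = 125 / 210,
                                  n_samples = 10, amp_log2 = 1.0,
                                  recurrence_rate = 0.8,
                                  background_rate = 1,
                                  probe_spacing = 5500, seed = 1) {
  stopifnot(driver_fraction >= 0, driver_fraction <= 1,
            split_fraction > 0, split_fraction < 1, n_genes >= 2)
  set.seed(seed)
  L <- human_region_len
  split <- floor(L * split_fraction)
  synteny <- data.frame(
    human_chrom = "hchr8", h_start = c(0, split), h_end = c(split, L),
    dog_chrom = c("dchr13", "dchr29"), d_start = c(0, 0),
    d_end = c(split, L - split),
    orientation = c("+", "-"), stringsAsFactors = FALSE)

  gmid <- floor((seq_len(n_genes) - 0.5) / n_genes * L)
  gw <- max(2, min(10000, floor(L / n_genes / 4)))
  human_genes <- data.frame(
    gene_id = sprintf("hg_%03d", seq_len(n_genes)), chrom = "hchr8",
    start = gmid - gw %/% 2, end = gmid + (gw - gw %/% 2),
    strand = "+", amplified = TRUE, stringsAsFactors = FALSE)

  # project gene midpoints into dog coordinates
  proj <- project_point(human_genes$chrom, gmid, synteny, from = "human")
  dog_genes <- data.frame(
    gene_id = human_genes$gene_id, chrom = proj$chrom,
    start = proj$pos - gw %/% 2, end = proj$pos + (gw - gw %/% 2),
    strand = "+", stringsAsFactors = FALSE)
  dog_genes$start <- pmax(dog_genes$start, 0)
  in_a <- dog_genes$chrom == "dchr13"
  n_a <- sum(in_a); n_b <- sum(!in_a)

  # drivers: a contiguous run of region-A genes
  n_drv <- round(driver_fraction * n_a)
  driver_ids <- character(0)
  if (n_drv > 0) {
    a_ids <- dog_genes$gene_id[in_a]
    a_ord <- a_ids[order(dog_genes$start[in_a])]
    s0 <- sample.int(n_a - n_drv + 1, 1)
    driver_ids <- a_ord[s0:(s0 + n_drv - 1)]
  }

  # dog genome model: region A and B chromosomes with jittered probes
  dog_len <- c(dchr13 = split, dchr29 = L - split)
  gm <- make_genome(n_chrom = 2, chrom_len = unname(dog_len),
                    gene_count = 2, probe_spacing = probe_spacing,
                    seed = seed + 101L)
  gm$chromosomes$chrom <- names(dog_len)
  gm$probes$chrom <- names(dog_len)[match(gm$probes$chrom,
                                          c("chr1", "chr2"))]
  gm$genes <- dog_genes

  # truth: driver amplicon recurrent across samples + random background
  truth <- list()
  if (n_drv > 0) {
    drv <- dog_genes[dog_genes$gene_id %in% driver_ids, ]
    span <- c(max(0, min(drv$start) - 1000), max(drv$end) + 1000)
  }
  for (s in seq_len(n_samples)) {
    sid <- sprintf("D%02d", s)
    if (n_drv > 0 && runif(1) < recurrence_rate) {
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = sid, chrom = "dchr13", start = span[1], end = span[2],
        log2 = amp_log2, class = "amp", stringsAsFactors = FALSE)
    }
    n_bg <- stats::rpois(1, background_rate)
    for (b in seq_len(n_bg)) {
      ch <- sample(names(dog_len), 1)
      blen <- floor(runif(1, 2e5, 1e6))
      bs <- floor(runif(1, 0, dog_len[[ch]] - blen))
      a <- runif(1, 0.6, 1) * sample(c(-1, 1), 1)
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = sid, chrom = ch, start = bs, end = bs + blen,
        log2 = a, class = if (a > 0) "amp" else "del",
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    simulate_cna_truth(gm, character(0))
  # background segments may collide with each other or the driver span;
  # resolve overlaps by keeping the earlier (driver segments are added first)
  truth <- drop_overlaps(truth)
  class(truth) <- c("cna_truth", "data.frame")

  list(synteny = synteny, human_genes = human_genes, dog_genome = gm,
       driver_ids = driver_ids, truth = truth,
       region_split = c(dchr13 = n_a, dchr29 = n_b))
}

#' False-discovery proportion of CNA calls against implanted truth
#'
#' A called (non-neutral) segment is a false discovery when it overlaps no
#' truth segment of the same sample and chromosome.
#'
#' @param calls Segment calls from [call_cnas()].
#' @param truth A [simulate_cna_truth()] table.
#' @return List with `n_called`, `n_false`, `fdp` (0 when nothing is
#'   called) and `false` (logical per called segment).
#' @export
cna_false_discovery <- function(calls, truth) {
  called <- calls[calls$call %in% c("amp", "del"), , drop = FALSE]
  if (nrow(called) == 0) {
    return(list(n_called = 0L, n_false = 0L, fdp = 0, false = logical(0)))
  }
  false <- vapply(seq_len(nrow(called)), function(i) {
    tt <- truth[truth$sample_id == called$sample_id[i] &
                  chrom_key(truth$chrom) == chrom_key(called$chrom[i]), ,
                drop = FALSE]
    !any(tt$start < called$end[i] & tt$end > called$start[i])
  }, logical(1))
  list(n_called = nrow(called), n_false = sum(false),
       fdp = mean(false), false = false)
}

# Keep the first of any pair of overlapping truth segments (per sample/chrom).
drop_overlaps <- function(truth) {
  keep <- rep(TRUE, nrow(truth))
  sp <- split(seq_len(nrow(truth)),
              paste(truth$sample_id, chrom_key(truth$chrom)))
  for (idx in sp) {
    taken <- matrix(numeric(0), ncol = 2)
    for (i in idx) {
      s <- truth$start[i]; e <- truth$end[i]
      if (nrow(taken) && any(s < taken[, 2] & e > taken[, 1])) {
        keep[i] <- FALSE
      } else {
        taken <- rbind(taken, c(s, e))
      }
    }
  }
  out <- truth[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
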