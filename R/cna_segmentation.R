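# Copy-number segmentation and FDR-controlled CNA calling.
#
# Two stages, mirroring change-point-based aCGH analysis: (1) per-chromosome
# least-squares change-point detection by exact dynamic programming; (2)
# genome-wide calling in which each segment's probe log2-ratios are tested
# against 0, p-values are Benjamini-Hochberg adjusted across the genome, and
# a segment is called amplified/deleted only if it additionally passes the
# probe-count and mean-amplitude cutoffs.

#' Segment one chromosome's log2-ratio profile
#'
#' For each candidate number of change-points `k = 0..max_k` the placement
#' minimising the Gaussian residual sum of squares is found exactly by
#' dynamic programming (O(k n^2)).  The reported `k` minimises
#' `RSS(k) + penalty * k`.  The default penalty is a modified-BIC value,
#' `2 * sigma^2 * log(n)`, with `sigma` estimated robustly from the median
#' absolute first difference of the profile (so that change-points
#' themselves barely inflate the estimate).  DP ties are broken towards the
#' leftmost breakpoint, making results deterministic.
#'
#' @param log2ratio Numeric vector of probe log2 ratios, in genomic order.
#' @param max_k Maximum number of change-points considered.
#' @param penalty Per-change-point penalty; `NULL` for the default above.
#' @return A list of class `chrom_segmentation`: `breakpoints` (indices `b`
#'   meaning a change between probes `b` and `b+1`, 1-based), `k`, `rss`
#'   (vector over k = 0..max_k), `breakpoints_by_k`, `penalty`, `sigma`.
#' @export
segment_chromosome <- function(log2ratio, max_k = 12, penalty = NULL) {
  x <- as.numeric(log2ratio)
  n <- length(x)
  if (n < 1) stop("empty profile")
  if (anyNA(x)) stop("NA log2 ratios are not allowed")
  max_k <- min(max_k, n - 1)
  dp <- dp_segment_rss(x, max_k)
  sigma <- robust_sigma(x)
  if (is.null(penalty)) penalty <- 2 * sigma^2 * log(max(n, 2))
  # numeric floor so that, when RSS reaches (numerical) zero, the smallest k
  # among equal-cost solutions is selected
  penalty <- max(penalty, 1e-8 * (dp$rss[1] + 1))
  cost <- dp$rss + penalty * (0:max_k)
  k <- which.min(cost) - 1L
  structure(list(breakpoints = dp$breakpoints[[k + 1]], k = k,
                 rss = dp$rss, breakpoints_by_k = dp$breakpoints,
                 penalty = penalty, sigma = sigma),
            class = "chrom_segmentation")
}

# MAD-type scale estimate from first differences: for i.i.d. Gaussian noise,
# diff(x) ~ N(0, 2 sigma^2), and median|Z| = 0.6745 sd.
robust_sigma <- function(x) {
  if (length(x) < 2) return(0)
  median(abs(diff(x))) / (0.6745 * sqrt(2))
}

# Turn breakpoints into a per-segment table for one chromosome of one sample.
segments_from_breakpoints <- function(values, positions, breakpoints,
                                      chrom, sample_id) {
  n <- length(values)
  bounds <- c(0L, sort(breakpoints), n)
  first <- head(bounds, -1) + 1L
  last <- tail(bounds, -1)
  data.frame(
    sample_id = sample_id, chrom = chrom,
    start = positions[first], end = positions[last] + 1,
    first_probe = first, last_probe = last,
    probe_count = last - first + 1L,
    mean_log2 = vapply(seq_along(first), function(i)
      mean(values[first[i]:last[i]]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Segment and call CNAs genome-wide
#'
#' Runs [segment_chromosome()] on every (sample, chromosome) profile, then
#' tests each segment's probe log2-ratios against 0 with a one-sample
#' t-test, adjusts p-values by Benjamini-Hochberg across all testable
#' segments of the sample's genome, and calls a segment:
#' * `amp`  if `mean_log2 >= +mean_cutoff`, `q <= fdr`, `probe_count >= min_probes`;
#' * `del`  if `mean_log2 <= -mean_cutoff` with the same side conditions;
#' * `neutral` otherwise.
#'
#' A segment with zero probe variance is treated as carrying unbounded
#' evidence: p = 0 when its mean is nonzero, p = 1 otherwise (the t statistic
#' is undefined there, but the noise-free limit is unambiguous).  Chromosomes
#' in `exclude_chroms` are segmented for completeness but receive no calls
#' and are excluded from the FDR adjustment; excluding the X chromosome by
#' default avoids artifacts from sex-mismatched tumor/reference pairs.
#'
#' @param probes Probe table: columns `chrom`, `pos`, then one numeric
#'   column per sample (see [read_probe_tsv()]).
#' @param fdr Desired false discovery rate across segments.
#' @param min_probes Minimum probes per called segment.
#' @param mean_cutoff Minimum absolute segment mean (log2) for a call.
#' @param exclude_chroms Chromosome names (with or without "chr" prefix)
#'   excluded from calling.
#' @param max_k,penalty Passed to [segment_chromosome()].
#' @return `data.frame` of segment calls: sample_id, chrom, start, end
#'   (0-based half-open, `[first probe pos, last probe pos + 1)`),
#'   probe_count, mean_log2, p_value, q_value, call, excluded.
#' @export
call_cnas <- function(probes, fdr = 0.01, min_probes = 3, mean_cutoff = 0.4,
                      exclude_chroms = "chrX", max_k = 12, penalty = NULL) {
  stopifnot(fdr > 0, fdr < 1, min_probes >= 1, mean_cutoff >= 0)
  stopifnot_cols(probes, c("chrom", "pos"), "probe table")
  samples <- setdiff(names(probes), c("chrom", "pos"))
  if (!length(samples)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      probe_count = integer(), mean_log2 = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      call = character(), excluded = logical(),
                      stringsAsFactors = FALSE))
  }
  excl_key <- chrom_key(exclude_chroms)
  segs <- list()
  for (sid in samples) {
    for (ch in unique(probes$chrom)) {
      idx <- probes$chrom == ch
      pos <- probes$pos[idx]
      o <- order(pos)
      vals <- probes[[sid]][idx][o]
      fit <- segment_chromosome(vals, max_k = max_k, penalty = penalty)
      sg <- segments_from_breakpoints(vals, pos[o], fit$breakpoints, ch, sid)
      sg$p_value <- vapply(seq_len(nrow(sg)), function(i) {
        v <- vals[sg$first_probe[i]:sg$last_probe[i]]
        segment_p(v)
      }, numeric(1))
      sg$excluded <- chrom_key(ch) %in% excl_key
      segs[[length(segs) + 1]] <- sg
    }
  }
  calls <- do.call(rbind, segs)
  calls$q_value <- NA_real_
  calls$call <- "neutral"
  for (sid in samples) {
    sel <- calls$sample_id == sid & !calls$excluded & !is.na(calls$p_value)
    calls$q_value[sel] <- p.adjust(calls$p_value[sel], method = "BH")
  }
  pass <- !calls$excluded & !is.na(calls$q_value) &
    calls$q_value <= fdr & calls$probe_count >= min_probes
  calls$call[pass & calls$mean_log2 >= mean_cutoff] <- "amp"
  calls$call[pass & calls$mean_log2 <= -mean_cutoff] <- "del"
  calls$first_probe <- calls$last_probe <- NULL
  rownames(calls) <- NULL
  calls
}

# One-sample location test of probe ratios against 0.
segment_p <- function(v) {
  if (length(v) < 2) return(NA_real_)           # single probe: untestable
  if (sd(v) == 0) return(if (mean(v) == 0) 1 else 0)  # noise-free limit
  t.test(v, mu = 0)$p.value
}

#' Summarize called CNAs per sample
#'
#' @param calls Output of [call_cnas()].
#' @return A list with `per_sample` (sample_id, amp_bp, del_bp, n_amp,
#'   n_del) and `sizes` (sample_id, class, size_bp; one row per called
#'   segment).
#' @export
genome_cna_summary <- function(calls) {
  called <- calls[calls$call %in% c("amp", "del"), , drop = FALSE]
  sizes <- data.frame(sample_id = called$sample_id, class = called$call,
                      size_bp = called$end - called$start,
                      stringsAsFactors = FALSE)
  sids <- unique(calls$sample_id)
  per <- data.frame(
    sample_id = sids,
    amp_bp = vapply(sids, function(s) sum(sizes$size_bp[
      sizes$sample_id == s & sizes$class == "amp"]), numeric(1)),
    del_bp = vapply(sids, function(s) sum(sizes$size_bp[
      sizes$sample_id == s & sizes$class == "del"]), numeric(1)),
    n_amp = vapply(sids, function(s) sum(sizes$sample_id == s &
                                           sizes$class == "amp"), numeric(1)),
    n_del = vapply(sids, function(s) sum(sizes$sample_id == s &
                                           sizes$class == "del"), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_sample = per, sizes = sizes)
}
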