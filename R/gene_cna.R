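# Gene-level CNA status and recurrence scoring across samples.
#
# Recurrence is scored with a permutation analog of GISTIC's G-score: per
# gene, the summed positive (or negative) amplitude across samples, compared
# against a null built from within-sample cyclic shifts of the gene-level
# amplitude vectors.  Cyclic shifts preserve each sample's total CNA burden
# and the spatial autocorrelation of its profile, so the null asks exactly
# "could this pile-up arise by chance placement of the same CNAs?".

#' Map segment calls onto genes
#'
#' A gene takes the call of the segment containing its midpoint; when the
#' midpoint falls in a probe gap between two segments, the nearer flanking
#' segment is used.  Genes on chromosomes that were excluded from calling
#' get status 0 with `excluded = TRUE`.
#'
#' @param calls Segment calls from [call_cnas()].
#' @param genes Gene table: gene_id, chrom, start, end (0-based half-open).
#' @return An object of class `gene_cna`: list with `genes` (the input plus
#'   `excluded`), `status` (genes x samples matrix in {-1, 0, +1}) and
#'   `amplitude` (mean log2 of the assigning segment).
#' @export
assign_gene_status <- function(calls, genes) {
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  samples <- unique(calls$sample_id)
  call_chroms <- unique(chrom_key(calls$chrom))
  gkey <- chrom_key(genes$chrom)
  if (!all(gkey %in% call_chroms)) {
    stop("gene on a chromosome with no segments: ",
         genes$chrom[which(!gkey %in% call_chroms)[1]])
  }
  mid <- (genes$start + genes$end) / 2
  status <- matrix(0L, nrow(genes), length(samples),
                   dimnames = list(genes$gene_id, samples))
  amplitude <- matrix(0, nrow(genes), length(samples),
                      dimnames = list(genes$gene_id, samples))
  excluded <- logical(nrow(genes))
  for (sid in samples) {
    cs <- calls[calls$sample_id == sid, , drop = FALSE]
    for (ch in unique(gkey)) {
      seg <- cs[chrom_key(cs$chrom) == ch, , drop = FALSE]
      gi <- which(gkey == ch)
      if (!nrow(seg)) next
      seg <- seg[order(seg$start), ]
      for (g in gi) {
        m <- mid[g]
        inside <- which(m >= seg$start & m < seg$end)
        j <- if (length(inside)) inside[1] else {
          # midpoint in a gap (or beyond the probe range): nearest segment
          d <- pmax(seg$start - m, 0) + pmax(m - seg$end, 0)
          which.min(d)
        }
        excluded[g] <- isTRUE(seg$excluded[j])
        amplitude[g, sid] <- seg$mean_log2[j]
        status[g, sid] <- switch(seg$call[j], amp = 1L, del = -1L, 0L)
      }
    }
  }
  genes$excluded <- excluded
  structure(list(genes = genes, status = status, amplitude = amplitude),
            class = "gene_cna")
}

#' Construct a gene_cna object from matrices
#'
#' Mainly for simulation and testing: wraps pre-computed status and
#' amplitude matrices in the container [assign_gene_status()] produces.
#'
#' @param genes Gene table (gene_id, chrom, start, end).
#' @param status Integer matrix genes x samples in {-1, 0, +1}.
#' @param amplitude Numeric matrix genes x samples, mean log2 per gene.
#' @export
new_gene_cna <- function(genes, status, amplitude = NULL) {
  stopifnot(nrow(status) == nrow(genes))
  if (is.null(amplitude)) amplitude <- status * 1.0
  rownames(status) <- rownames(amplitude) <- genes$gene_id
  if (is.null(genes$excluded)) genes$excluded <- FALSE
  structure(list(genes = genes, status = status, amplitude = amplitude),
            class = "gene_cna")
}

#' @export
print.gene_cna <- function(x, ...) {
  cat(sprintf("gene_cna: %d genes x %d samples (%d amp, %d del entries)\n",
              nrow(x$status), ncol(x$status), sum(x$status == 1),
              sum(x$status == -1)))
  invisible(x)
}

# Shift each column of A cyclically by its offset (0 <= off < nrow).
# Redistributes, never creates or destroys, amplitude: column sums and the
# per-column value multiset are preserved exactly.
cyclic_shift <- function(A, off) {
  n <- nrow(A)
  for (s in seq_len(ncol(A))) {
    if (off[s] > 0) A[, s] <- A[c((off[s] + 1):n, 1:off[s]), s]
  }
  A
}

#' Score gene-level CNA recurrence across samples
#'
#' Per-gene amplification score: sum over samples of `max(0, amplitude)`
#' (deletion score mirrored with `max(0, -amplitude)`).  The null
#' distribution pools gene scores over `n_perm` permutations in which each
#' sample's gene-amplitude vector is cyclically shifted along the genome
#' gene order by an independent random offset.  Empirical p-values are
#' Benjamini-Hochberg adjusted; genes with `q <= fdr` are flagged recurrent.
#'
#' @param gene_cna A [assign_gene_status()] / [new_gene_cna()] object.
#'   Genes must be (and are re-)ordered by genome position.
#' @param n_perm Number of permutations (>= 100).
#' @param fdr Recurrence FDR threshold.
#' @param seed Integer seed for the shift offsets.
#' @return `data.frame` per gene: gene_id, chrom, start, end, score_amp,
#'   p_amp, q_amp, recurrent_amp, and the deletion counterparts.
#' @export
recurrence_test <- function(gene_cna, n_perm = 1000, fdr = 0.2, seed = 1) {
  stopifnot(inherits(gene_cna, "gene_cna"))
  if (ncol(gene_cna$status) < 2) stop("recurrence needs >= 2 samples")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (n_perm < 10 / fdr) {
    warning(sprintf("n_perm = %d gives coarse p-value resolution for fdr = %g",
                    n_perm, fdr))
  }
  g <- gene_cna$genes
  ord <- order(g$chrom, g$start)
  g <- g[ord, , drop = FALSE]
  A <- gene_cna$amplitude[ord, , drop = FALSE]
  n_gene <- nrow(A); n_samp <- ncol(A)

  score <- function(M) rowSums(pmax(M, 0))
  obs_amp <- score(A)
  obs_del <- score(-A)

  set.seed(seed)
  null_amp <- numeric(n_gene * n_perm)
  null_del <- numeric(n_gene * n_perm)
  for (p in seq_len(n_perm)) {
    off <- sample.int(n_gene, n_samp, replace = TRUE) - 1L
    Ap <- cyclic_shift(A, off)
    idx <- ((p - 1) * n_gene + 1):(p * n_gene)
    null_amp[idx] <- score(Ap)
    null_del[idx] <- score(-Ap)
  }
  p_emp <- function(obs, null) {
    ns <- sort(null)
    n <- length(ns)
    # count of null >= obs via binary search on the sorted null
    (1 + (n - findInterval(obs - 1e-12, ns))) / (n + 1)
  }
  p_amp <- p_emp(obs_amp, null_amp)
  p_del <- p_emp(obs_del, null_del)
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                    end = g$end,
                    score_amp = obs_amp, p_amp = p_amp,
                    q_amp = p.adjust(p_amp, "BH"),
                    score_del = obs_del, p_del = p_del,
                    q_del = p.adjust(p_del, "BH"),
                    stringsAsFactors = FALSE)
  out$recurrent_amp <- out$q_amp <= fdr & out$score_amp > 0
  out$recurrent_del <- out$q_del <= fdr & out$score_del > 0
  rownames(out) <- NULL
  out
}
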