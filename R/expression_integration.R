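# Copy-number / expression integration.
#
# Expression is classified low/normal/high per gene against the samples that
# are copy-neutral (diploid) for that gene.  The interval used is a
# *prediction* interval for one new observation,
#   mean +/- t_{1-alpha/2, n-1} * s * sqrt(1 + 1/n),
# on log2(FPKM + 1): under a Gaussian null it classifies a fraction alpha of
# held-out diploid samples as non-normal, which is the evident intent of an
# outlier rule (a plain confidence interval for the mean would flag far more
# than alpha).  Diploid reference samples are classified against the
# leave-one-out interval to avoid self-inclusion bias.

#' Filter to expressed genes
#'
#' Keeps genes whose value is `>= min_fpkm` (inclusive) in at least
#' `min_samples` samples.
#'
#' @param mat Numeric matrix genes x samples, FPKM scale.
#' @param min_fpkm Expression floor.
#' @param min_samples Minimum number of samples at or above the floor.
#' @export
filter_expressed <- function(mat, min_fpkm = 1, min_samples = 1) {
  keep <- rowSums(mat >= min_fpkm) >= min_samples
  mat[keep, , drop = FALSE]
}

#' Prediction interval from diploid reference values
#'
#' @param values Log-scale expression values of the diploid samples.
#' @param alpha Two-sided miss rate; 0.05 gives a 95% interval.
#' @return `c(lo, hi)`; degenerate (lo == hi) when the values have zero
#'   variance.
#' @export
diploid_interval <- function(values, alpha = 0.05) {
  n <- length(values)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  m <- mean(values); s <- sd(values)
  h <- qt(1 - alpha / 2, n - 1) * s * sqrt(1 + 1 / n)
  c(lo = m - h, hi = m + h)
}

#' Classify expression low/normal/high against diploid reference samples
#'
#' @param mat Numeric matrix genes x samples, FPKM scale.
#' @param gene_cna A `gene_cna` object (or a genes x samples status matrix)
#'   aligned by gene id and sample name with `mat`.
#' @param alpha Interval miss rate (0.05 = 95% interval).
#' @param min_diploid Minimum diploid reference samples per gene; genes
#'   below this are `unclassifiable`.
#' @param pseudocount Added before the log2 transform.
#' @return `data.frame` with gene_id, sample_id, level (`low`/`normal`/
#'   `high`/`unclassifiable`), lo, hi, n_diploid, degenerate.
#' @export
classify_expression <- function(mat, gene_cna, alpha = 0.05,
                                min_diploid = 3, pseudocount = 1) {
  status <- if (inherits(gene_cna, "gene_cna")) gene_cna$status else gene_cna
  common_g <- intersect(rownames(mat), rownames(status))
  common_s <- intersect(colnames(mat), colnames(status))
  if (!length(common_g) || length(common_s) < 2) {
    stop("expression matrix and CNA status share too few genes/samples")
  }
  lg <- log2(mat[common_g, common_s, drop = FALSE] + pseudocount)
  st <- status[common_g, common_s, drop = FALSE]

  res <- vector("list", length(common_g))
  for (i in seq_along(common_g)) {
    v <- lg[i, ]
    dip <- which(st[i, ] == 0)
    n_dip <- length(dip)
    if (n_dip < min_diploid) {
      res[[i]] <- data.frame(gene_id = common_g[i], sample_id = common_s,
                             level = "unclassifiable", lo = NA_real_,
                             hi = NA_real_, n_diploid = n_dip,
                             degenerate = FALSE, stringsAsFactors = FALSE)
      next
    }
    iv <- diploid_interval(v[dip], alpha)
    lev <- character(length(v)); lo <- numeric(length(v)); hi <- lo
    deg <- logical(length(v))
    for (j in seq_along(v)) {
      if (j %in% dip) {
        ivj <- diploid_interval(v[setdiff(dip, j)], alpha)
      } else {
        ivj <- iv
      }
      lo[j] <- ivj[1]; hi[j] <- ivj[2]
      deg[j] <- ivj[1] == ivj[2]
      lev[j] <- if (v[j] > ivj[2]) "high" else
        if (v[j] < ivj[1]) "low" else "normal"
    }
    res[[i]] <- data.frame(gene_id = common_g[i], sample_id = common_s,
                           level = lev, lo = lo, hi = hi, n_diploid = n_dip,
                           degenerate = deg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (any(out$degenerate)) {
    warning(sprintf(
      "%d classification(s) used a zero-variance (degenerate) interval",
      sum(out$degenerate)))
  }
  rownames(out) <- NULL
  out
}

#' Copy-number x expression concordance table
#'
#' Cross-tabulates gene-sample pairs by CNA group (Del / unchanged / Amp)
#' and expression level (low / normal / high), as percentages within each
#' CNA group (columns sum to 100).
#'
#' @param calls Output of [classify_expression()].
#' @param gene_cna `gene_cna` object or status matrix.
#' @return 3x3 numeric matrix (rows low/normal/high, columns
#'   Del/unchanged/Amp) of percentages; attribute `"counts"` holds the raw
#'   counts.
#' @export
concordance_table <- function(calls, gene_cna) {
  status <- if (inherits(gene_cna, "gene_cna")) gene_cna$status else gene_cna
  cc <- calls[calls$level %in% c("low", "normal", "high"), , drop = FALSE]
  grp <- status[cbind(match(cc$gene_id, rownames(status)),
                      match(cc$sample_id, colnames(status)))]
  grp <- factor(c("Del", "unchanged", "Amp")[grp + 2],
                levels = c("Del", "unchanged", "Amp"))
  lev <- factor(cc$level, levels = c("low", "normal", "high"))
  counts <- table(lev, grp)
  pct <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
  out <- matrix(as.numeric(pct), 3, 3,
                dimnames = list(rownames(counts), colnames(counts)))
  attr(out, "counts") <- unclass(counts)
  out
}

#' Differential expression by Welch t-tests
#'
#' Per-gene Welch (unequal-variance) t-test of log2(FPKM + pseudocount)
#' between two sample groups, with Benjamini-Hochberg adjustment.
#'
#' @param mat Numeric matrix genes x samples, FPKM scale.
#' @param group1_ids,group2_ids Sample names of the two groups (e.g. tumors
#'   and normals); each needs >= 2 samples.
#' @param fdr Significance threshold on q.
#' @param pseudocount Added before the log2 transform.
#' @return `data.frame` per gene: gene_id, mean1, mean2, t, df, p, q,
#'   direction (sign of mean1 - mean2), significant.
#' @export
differential_expression_ttest <- function(mat, group1_ids, group2_ids,
                                          fdr = 0.1, pseudocount = 1) {
  stopifnot(length(group1_ids) >= 2, length(group2_ids) >= 2,
            all(c(group1_ids, group2_ids) %in% colnames(mat)))
  x <- log2(mat[, group1_ids, drop = FALSE] + pseudocount)
  y <- log2(mat[, group2_ids, drop = FALSE] + pseudocount)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # zero variance in both groups: identical values => no evidence, else
  # unbounded evidence (noise-free limit)
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  q <- p.adjust(p, "BH")
  data.frame(gene_id = rownames(mat), mean1 = m1, mean2 = m2, t = t,
             df = df, p = p, q = q,
             direction = sign(m1 - m2), significant = q <= fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the multivariate means of two groups of gene-level feature
#' vectors (typically bivariate: mean log2 copy ratio, mean log2
#' expression).  The statistic is converted to an F with
#' `F = T2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))` on
#' `(p, n1 + n2 - p - 1)` degrees of freedom.  With p = 1 it reduces to the
#' squared pooled-variance two-sample t statistic.
#'
#' @param group_a,group_b Numeric matrices (rows = genes, columns =
#'   features) with the same columns; each needs more rows than features.
#' @return List with `t2`, `f`, `df1`, `df2`, `p_value`, `n` (group sizes).
#' @export
hotelling_concordance <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  p <- ncol(A)
  stopifnot(ncol(B) == p, p >= 1)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 3 || n2 < 3) stop("each group needs >= 3 observations")
  if (n1 + n2 - p - 1 <= 0) stop("too few observations for the dimension")
  d <- colMeans(A) - colMeans(B)
  S <- ((n1 - 1) * stats::cov(A) + (n2 - 1) * stats::cov(B)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; jitter the features or drop a dimension",
         call. = FALSE))
  t2 <- as.numeric((n1 * n2) / (n1 + n2) * t(d) %*% Sinv %*% d)
  f <- t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  list(t2 = t2, f = f, df1 = p, df2 = n1 + n2 - p - 1,
       p_value = pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE),
       n = c(n1, n2))
}
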