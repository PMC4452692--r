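# Cross-species driver-versus-passenger discrimination.
#
# A recurrently amplified region in genome 1 ("human") is projected through
# a synteny block map into genome 2 ("dog"), where interspecies
# rearrangement may split it into several regions.  Genes whose dog region
# is also recurrently amplified are driver candidates (DCGs); genes whose
# dog region is copy-neutral are passenger candidates (PCGs).  The
# amplified/unchanged split between regions is tested with Fisher's exact
# test.

#' Project a point through a synteny map
#'
#' @param chrom,pos Vectors of source chromosome and position (0-based).
#' @param map Synteny block table (see [read_synteny_tsv()]).
#' @param from `"human"` to map human -> dog, `"dog"` for the inverse.
#' @return `data.frame` with target `chrom` and `pos` (NA when unmapped).
#' @export
project_point <- function(chrom, pos, map, from = c("human", "dog")) {
  from <- match.arg(from)
  map <- validate_synteny(map)
  if (from == "human") {
    s_chr <- map$human_chrom; s_s <- map$h_start; s_e <- map$h_end
    t_chr <- map$dog_chrom; t_s <- map$d_start; t_e <- map$d_end
  } else {
    s_chr <- map$dog_chrom; s_s <- map$d_start; s_e <- map$d_end
    t_chr <- map$human_chrom; t_s <- map$h_start; t_e <- map$h_end
  }
  out_chr <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_real_, length(pos))
  key <- chrom_key(chrom)
  for (b in seq_len(nrow(map))) {
    hit <- key == chrom_key(s_chr[b]) & pos >= s_s[b] & pos < s_e[b]
    if (!any(hit)) next
    off <- pos[hit] - s_s[b]
    out_chr[hit] <- t_chr[b]
    out_pos[hit] <- if (map$orientation[b] == "+") t_s[b] + off else
      t_e[b] - 1 - off
  }
  data.frame(chrom = out_chr, pos = out_pos, stringsAsFactors = FALSE)
}

#' Project an interval through a synteny map
#'
#' Piecewise-linear coordinate transfer: the query interval is intersected
#' with each overlapping block and transferred linearly, with offsets
#' reversed for blocks of orientation `"-"`.  Unmapped sub-intervals are
#' reported, never silently dropped.  On mapped bases the projection is
#' invertible (project the result with the opposite `from` to return).
#'
#' @param chrom Source chromosome.
#' @param start,end Source interval, 0-based half-open.
#' @param map Synteny block table.
#' @param from `"human"` or `"dog"`.
#' @return List with `regions` (target chrom, start, end, orientation, plus
#'   the source sub-interval src_start/src_end each derives from) and
#'   `unmapped` (source sub-intervals with no block).  A fully unmapped
#'   query gives zero regions with a warning.
#' @export
project_region <- function(chrom, start, end, map, from = c("human", "dog")) {
  from <- match.arg(from)
  stopifnot(length(chrom) == 1, end > start)
  map <- validate_synteny(map)
  if (from == "human") {
    s_chr <- map$human_chrom; s_s <- map$h_start; s_e <- map$h_end
    t_chr <- map$dog_chrom; t_s <- map$d_start; t_e <- map$d_end
  } else {
    s_chr <- map$dog_chrom; s_s <- map$d_start; s_e <- map$d_end
    t_chr <- map$human_chrom; t_s <- map$h_start; t_e <- map$h_end
  }
  ord <- order(s_s)
  regions <- list(); covered <- list()
  for (b in ord) {
    if (chrom_key(s_chr[b]) != chrom_key(chrom)) next
    a <- max(start, s_s[b]); z <- min(end, s_e[b])
    if (z <= a) next
    off_a <- a - s_s[b]; off_z <- z - s_s[b]
    if (map$orientation[b] == "+") {
      ts <- t_s[b] + off_a; te <- t_s[b] + off_z
    } else {
      ts <- t_e[b] - off_z; te <- t_e[b] - off_a
    }
    regions[[length(regions) + 1]] <- data.frame(
      chrom = t_chr[b], start = ts, end = te,
      orientation = map$orientation[b], src_start = a, src_end = z,
      stringsAsFactors = FALSE)
    covered[[length(covered) + 1]] <- c(a, z)
  }
  unmapped <- gaps_in_cover(start, end, covered)
  if (!length(regions)) {
    warning(sprintf("region %s:%d-%d is entirely unmapped", chrom,
                    start, end))
    regions_df <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), orientation = character(),
                             src_start = numeric(), src_end = numeric(),
                             stringsAsFactors = FALSE)
  } else {
    regions_df <- do.call(rbind, regions)
  }
  list(regions = regions_df, unmapped = unmapped)
}

gaps_in_cover <- function(start, end, covered) {
  if (!length(covered)) {
    return(data.frame(start = start, end = end))
  }
  m <- do.call(rbind, covered)
  m <- m[order(m[, 1]), , drop = FALSE]
  gaps <- list(); cur <- start
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] > cur) gaps[[length(gaps) + 1]] <- c(cur, m[i, 1])
    cur <- max(cur, m[i, 2])
  }
  if (cur < end) gaps[[length(gaps) + 1]] <- c(cur, end)
  if (!length(gaps)) return(data.frame(start = numeric(), end = numeric()))
  g <- do.call(rbind, gaps)
  data.frame(start = g[, 1], end = g[, 2])
}

#' Discriminate driver from passenger candidates across projected regions
#'
#' Dog genes are assigned to the projected region containing their midpoint
#' and labelled amplified (`q_amp <= fdr`), deleted (`q_del <= fdr`, kept
#' out of both candidate sets) or unchanged.  With two regions the
#' amplified/unchanged counts form a single 2x2 Fisher test; with more,
#' each region is tested one-vs-rest and BH-adjusted.  When the test is
#' significant, DCGs are the amplified genes of the region(s) with
#' amplified fraction above the overall mean, and PCGs the unchanged genes
#' of the remaining region(s).
#'
#' @param recurrence Dog gene recurrence table from [recurrence_test()].
#' @param human_genes Human gene table with a logical `amplified` column;
#'   all genes in the projected region must be amplified (the strategy
#'   applies to human-recurrent amplicons).
#' @param regions Projected dog regions (`regions` element of
#'   [project_region()], or any table with chrom/start/end).
#' @param fdr Recurrence threshold applied to q_amp / q_del.
#' @param alpha Significance level for the discrimination test.
#' @return List of class `driver_passenger_result`: `per_region` counts,
#'   `table` (2x2 for the two-region case), `odds_ratio`, `p_value`,
#'   `dcg_ids`, `pcg_ids`, `deleted_ids`, `status`
#'   (`"discriminated"`/`"no_discrimination"`).
#' @export
discriminate_drivers <- function(recurrence, human_genes, regions,
                                 fdr = 0.2, alpha = 0.05) {
  if (nrow(regions) < 2) {
    stop("driver-passenger discrimination needs >= 2 projected regions ",
         "(a synteny break); got ", nrow(regions))
  }
  if (!is.null(human_genes$amplified) && !all(human_genes$amplified)) {
    stop("all human genes in the region must be amplified; the strategy ",
         "applies to recurrently amplified human regions only")
  }
  mid <- (recurrence$start + recurrence$end) / 2
  region_of <- rep(NA_integer_, nrow(recurrence))
  for (r in seq_len(nrow(regions))) {
    hit <- chrom_key(recurrence$chrom) == chrom_key(regions$chrom[r]) &
      mid >= regions$start[r] & mid < regions$end[r]
    region_of[is.na(region_of) & hit] <- r
  }
  g <- recurrence[!is.na(region_of), , drop = FALSE]
  reg <- region_of[!is.na(region_of)]
  state <- ifelse(g$q_amp <= fdr, "amplified",
                  ifelse(g$q_del <= fdr, "deleted", "unchanged"))

  per_region <- data.frame(
    region = seq_len(nrow(regions)),
    chrom = regions$chrom, start = regions$start, end = regions$end,
    n_amplified = vapply(seq_len(nrow(regions)), function(r)
      sum(reg == r & state == "amplified"), numeric(1)),
    n_unchanged = vapply(seq_len(nrow(regions)), function(r)
      sum(reg == r & state == "unchanged"), numeric(1)),
    n_deleted = vapply(seq_len(nrow(regions)), function(r)
      sum(reg == r & state == "deleted"), numeric(1)),
    stringsAsFactors = FALSE)

  if (nrow(regions) == 2) {
    tab <- matrix(c(per_region$n_amplified[1], per_region$n_unchanged[1],
                    per_region$n_amplified[2], per_region$n_unchanged[2]),
                  2, 2, dimnames = list(c("amplified", "unchanged"),
                                        c("region1", "region2")))
    ft <- fisher.test(tab)
    p <- ft$p.value; or <- unname(ft$estimate)
    region_p <- c(p, p)
  } else {
    tab <- NULL; or <- NA_real_
    region_p <- vapply(seq_len(nrow(regions)), function(r) {
      m <- matrix(c(per_region$n_amplified[r], per_region$n_unchanged[r],
                    sum(per_region$n_amplified[-r]),
                    sum(per_region$n_unchanged[-r])), 2, 2)
      fisher.test(m)$p.value
    }, numeric(1))
    region_p <- p.adjust(region_p, "BH")
    p <- min(region_p)
  }
  per_region$p <- region_p

  tot <- per_region$n_amplified + per_region$n_unchanged
  frac <- ifelse(tot > 0, per_region$n_amplified / tot, 0)
  if (p <= alpha) {
    driver_regions <- which(frac > sum(per_region$n_amplified) /
                              max(sum(tot), 1))
    dcg <- g$gene_id[state == "amplified" & reg %in% driver_regions]
    pcg <- g$gene_id[state == "unchanged" & !(reg %in% driver_regions)]
    status <- "discriminated"
  } else {
    dcg <- character(0); pcg <- character(0)
    status <- "no_discrimination"
  }
  structure(list(per_region = per_region, table = tab, odds_ratio = or,
                 p_value = p, dcg_ids = dcg, pcg_ids = pcg,
                 deleted_ids = g$gene_id[state == "deleted"],
                 status = status),
            class = "driver_passenger_result")
}

#' @export
print.driver_passenger_result <- function(x, ...) {
  cat(sprintf("driver-passenger discrimination: %s (p = %.3g)\n",
              x$status, x$p_value))
  cat(sprintf("  %d DCGs, %d PCGs, %d deleted genes set aside\n",
              length(x$dcg_ids), length(x$pcg_ids), length(x$deleted_ids)))
  invisible(x)
}

#' Test mutation enrichment of DCGs over PCGs
#'
#' 2x2 Fisher's exact test of (mutated, not mutated) x (DCG, PCG).
#'
#' @param dcg_ids,pcg_ids Disjoint gene id sets.
#' @param mutated_ids Gene ids observed mutated (e.g. in an independent
#'   cohort).
#' @return List with `table`, `odds_ratio`, `p_value`.
#' @export
validate_mutation_enrichment <- function(dcg_ids, pcg_ids, mutated_ids) {
  if (length(intersect(dcg_ids, pcg_ids))) {
    stop("DCG and PCG sets must be disjoint")
  }
  tab <- matrix(c(sum(dcg_ids %in% mutated_ids),
                  sum(!dcg_ids %in% mutated_ids),
                  sum(pcg_ids %in% mutated_ids),
                  sum(!pcg_ids %in% mutated_ids)), 2, 2,
                dimnames = list(c("mutated", "not_mutated"),
                                c("DCG", "PCG")))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Compare copy/expression concordance of DCGs vs PCGs
#'
#' Each gene contributes a bivariate feature (mean log2 copy ratio, mean
#' log2 expression); the two sets are compared with Hotelling's T-squared
#' via [hotelling_concordance()].
#'
#' @param dcg_ids,pcg_ids Gene id sets.
#' @param features Numeric matrix or data.frame with row names = gene ids
#'   and two feature columns.
#' @return As [hotelling_concordance()].
#' @export
validate_concordance <- function(dcg_ids, pcg_ids, features) {
  features <- as.matrix(features)
  a <- features[rownames(features) %in% dcg_ids, , drop = FALSE]
  b <- features[rownames(features) %in% pcg_ids, , drop = FALSE]
  hotelling_concordance(a, b)
}
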