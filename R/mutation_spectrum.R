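# Substitution-spectrum analysis.
#
# Substitutions are strand-collapsed onto the six pyrimidine-reference
# classes {C>A, C>G, C>T, T>A, T>C, T>G}; context flags (CpG, TpC) are
# likewise strand-symmetric.  Virus-status groups are compared by pooling
# CpG-site counts within each group (individual samples carry too few CpG
# events for per-sample tests) and applying a two-sided Fisher's exact test.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Filter variant records by read depth
#'
#' Keeps records with `min_depth <= depth <= max_depth` (both inclusive),
#' the accuracy filter used for mutation-finding from RNA-seq coverage.
#'
#' @param records Variant table (see [read_vcf()]).
#' @param min_depth,max_depth Inclusive depth bounds.
#' @export
filter_by_coverage <- function(records, min_depth = 30, max_depth = 300) {
  stopifnot_cols(records, "depth", "variant table")
  if (anyNA(records$depth)) stop("records with missing depth")
  records[records$depth >= min_depth & records$depth <= max_depth, ,
          drop = FALSE]
}

#' Strand-collapse a substitution into one of six classes
#'
#' Purine-reference pairs are reverse-complemented onto the
#' pyrimidine-reference classes; e.g. G>A becomes C>T.  Transitions are
#' C>T and T>C.
#'
#' @param ref,alt Character vectors of single bases (vectorized).
#' @return `data.frame` with `class` and `is_transition`.
#' @export
collapse_class <- function(ref, alt) {
  stopifnot(length(ref) == length(alt),
            all(ref %in% c("A", "C", "G", "T")),
            all(alt %in% c("A", "C", "G", "T")), all(ref != alt))
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, BASE_COMP[ref], ref)
  a <- ifelse(pur, BASE_COMP[alt], alt)
  cls <- paste0(r, ">", a)
  data.frame(class = cls, is_transition = cls %in% c("C>T", "T>C"),
             stringsAsFactors = FALSE)
}

#' Annotate CpG and TpC context
#'
#' CpG: the mutated base is the C of a CpG dinucleotide on either strand
#' (ref C with 3' G, or ref G with 5' C).  TpC: after pyrimidine collapse
#' the mutated C has a 5' T (ref C with 5' T, or ref G with 3' A).  Records
#' with an `N` in the relevant flank get `NA` and are excluded from
#' CpG-restricted analyses.
#'
#' @param records Variant table with ref, five_prime, three_prime.
#' @return The input with logical columns `is_cpg` and `is_tpc` added.
#' @export
annotate_context <- function(records) {
  stopifnot_cols(records, c("ref", "five_prime", "three_prime"),
                 "variant table")
  r <- records$ref; f <- records$five_prime; t3 <- records$three_prime
  stopifnot(all(f %in% names(BASE_COMP)), all(t3 %in% names(BASE_COMP)))
  cpg <- ifelse(r == "C", t3 == "G", ifelse(r == "G", f == "C", FALSE))
  cpg[(r == "C" & t3 == "N") | (r == "G" & f == "N")] <- NA
  tpc <- ifelse(r == "C", f == "T", ifelse(r == "G", t3 == "A", FALSE))
  tpc[(r == "C" & f == "N") | (r == "G" & t3 == "N")] <- NA
  records$is_cpg <- cpg
  records$is_tpc <- tpc
  records
}

#' Per-sample substitution spectrum
#'
#' Counts and fractions over the six strand-collapsed classes, the
#' transition/transversion split, and the CpG-restricted versions of both.
#'
#' @param records Variant table; context columns are added if absent.
#' @return `data.frame`, one row per sample: n, the six class fractions,
#'   fraction_transition, fraction_transversion, n_cpg,
#'   cpg_fraction_transversion, fraction_tpc.  Class counts are kept in the
#'   `"counts"` attribute (samples x classes).  Samples with zero records
#'   after filtering get NA fractions.
#' @export
mutation_spectrum <- function(records) {
  stopifnot_cols(records, c("sample_id", "ref", "alt"), "variant table")
  if (is.null(records$is_cpg)) records <- annotate_context(records)
  cc <- collapse_class(records$ref, records$alt)
  records$class <- cc$class
  records$is_transition <- cc$is_transition
  sids <- unique(records$sample_id)
  counts <- matrix(0L, length(sids), 6, dimnames = list(sids, SUB_CLASSES))
  rows <- vector("list", length(sids))
  for (i in seq_along(sids)) {
    d <- records[records$sample_id == sids[i], , drop = FALSE]
    n <- nrow(d)
    tb <- table(factor(d$class, levels = SUB_CLASSES))
    counts[i, ] <- as.integer(tb)
    fr <- if (n > 0) as.numeric(tb) / n else rep(NA_real_, 6)
    cp <- d[!is.na(d$is_cpg) & d$is_cpg, , drop = FALSE]
    rows[[i]] <- data.frame(
      sample_id = sids[i], n = n,
      setNames(as.list(fr), paste0("frac_", gsub(">", "_", SUB_CLASSES))),
      fraction_transition = if (n > 0) mean(d$is_transition) else NA_real_,
      fraction_transversion = if (n > 0) mean(!d$is_transition) else NA_real_,
      n_cpg = nrow(cp),
      cpg_fraction_transversion = if (nrow(cp) > 0)
        mean(!cp$is_transition) else NA_real_,
      fraction_tpc = if (sum(!is.na(d$is_tpc)) > 0)
        mean(d$is_tpc, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Compare CpG-site transversion rates between two groups
#'
#' Restricts both record sets to CpG-context substitutions, pools counts
#' within each group, and tests the 2x2 table
#' (transversion, transition) x (group 1, group 2) with a two-sided
#' Fisher's exact test.  No direction is assumed; the per-group fractions
#' are returned so the direction can be read off.
#'
#' @param records_pos,records_neg Variant tables for the two groups (e.g.
#'   virus-positive and virus-negative tumors).
#' @return List with `table` (2x2 counts), `fractions` (per-group
#'   transversion fraction at CpG sites), `odds_ratio`, `p_value`.
#' @export
compare_cpg_transversions <- function(records_pos, records_neg) {
  prep <- function(d) {
    if (is.null(d$is_cpg)) d <- annotate_context(d)
    d <- d[!is.na(d$is_cpg) & d$is_cpg, , drop = FALSE]
    tv <- !collapse_class(d$ref, d$alt)$is_transition
    c(tv = sum(tv), ti = sum(!tv))
  }
  a <- prep(records_pos); b <- prep(records_neg)
  if (sum(a) == 0 || sum(b) == 0) stop("a group has no CpG-site records")
  tab <- matrix(c(a["tv"], a["ti"], b["tv"], b["ti"]), 2, 2,
                dimnames = list(c("transversion", "transition"),
                                c("group1", "group2")))
  if (any(rowSums(tab) == 0)) {
    warning("empty margin in CpG transversion table; p set to 1")
    return(list(table = tab,
                fractions = c(group1 = a[["tv"]] / sum(a),
                              group2 = b[["tv"]] / sum(b)),
                odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  list(table = tab,
       fractions = c(group1 = a[["tv"]] / sum(a),
                     group2 = b[["tv"]] / sum(b)),
       odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Classify the coding consequence of a substitution
#'
#' Applies the standard genetic code to a codon carrying the substitution.
#' For a gene on the minus strand pass `strand = "-"`: the genomic ref/alt
#' are complemented before being placed in the (coding-strand) codon.
#'
#' @param codon Three-base coding-strand codon containing the site.
#' @param pos_in_codon Position of the site within the codon, 0-2.
#' @param ref,alt Genomic reference and alternate base.
#' @param residue_index Optional 1-based residue number for the label
#'   (e.g. 233 gives `"E233K"`).
#' @param strand `"+"` or `"-"`.
#' @return List with `effect` (`synonymous`/`missense`/`nonsense`),
#'   `ref_aa`, `alt_aa`, `label`.
#' @export
classify_coding_effect <- function(codon, pos_in_codon, ref, alt,
                                   residue_index = NULL, strand = "+") {
  stopifnot(nchar(codon) == 3, pos_in_codon %in% 0:2,
            strand %in% c("+", "-"))
  codon <- toupper(codon)
  if (strand == "-") { ref <- BASE_COMP[[ref]]; alt <- BASE_COMP[[alt]] }
  bases <- strsplit(codon, "")[[1]]
  if (bases[pos_in_codon + 1] != ref) {
    stop(sprintf("codon %s position %d is %s, not ref %s",
                 codon, pos_in_codon, bases[pos_in_codon + 1], ref))
  }
  mut <- bases
  mut[pos_in_codon + 1] <- alt
  gc <- Biostrings::GENETIC_CODE
  aa1 <- unname(gc[codon])
  aa2 <- unname(gc[paste(mut, collapse = "")])
  effect <- if (aa2 == "*" && aa1 != "*") "nonsense" else
    if (aa1 == aa2) "synonymous" else "missense"
  label <- paste0(aa1, if (!is.null(residue_index)) residue_index else "",
                  aa2)
  list(effect = effect, ref_aa = aa1, alt_aa = aa2, label = label)
}
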