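# End-to-end pipeline orchestration.
#
# Stages run in dependency order: segment -> gene-cna -> integrate /
# spectrum -> discriminate.  Each stage's outputs are written before the
# next starts, so a failure leaves earlier outputs intact; the run report
# records per-stage record counts, parameters and the seed.

#' Build a validated run configuration
#'
#' @param probes Path to the probe-level log2-ratio TSV.
#' @param genes Path to the gene BED.
#' @param expression Path to the expression TSV (optional).
#' @param vcf,fasta Paths to the variant VCF and its reference FASTA
#'   (optional).
#' @param synteny Path to the synteny block map TSV (optional).
#' @param meta Path to the sample metadata TSV (optional).
#' @param human_region `list(chrom=, start=, end=)` of the human amplicon to
#'   project (optional, needs `synteny`).
#' @param out_dir Output directory (created if missing).
#' @param fdr_cna,min_probes,mean_cutoff Parameters of [call_cnas()].
#' @param exclude_chroms Chromosomes excluded from CNA calling.
#' @param recurrence_fdr,n_perm Parameters of [recurrence_test()].
#' @param expr_alpha Interval miss rate of [classify_expression()].
#' @param de_fdr FDR of [differential_expression_ttest()].
#' @param min_depth,max_depth Coverage filter bounds.
#' @param seed Root seed; module substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(probes, genes, expression = NULL, vcf = NULL,
                       fasta = NULL, synteny = NULL, meta = NULL,
                       human_region = NULL, out_dir = "crossonc_out",
                       fdr_cna = 0.01, min_probes = 3, mean_cutoff = 0.4,
                       exclude_chroms = "chrX", recurrence_fdr = 0.2,
                       n_perm = 1000, expr_alpha = 0.05, de_fdr = 0.1,
                       min_depth = 30, max_depth = 300, seed = 1) {
  stopifnot(fdr_cna > 0, fdr_cna < 1, min_probes >= 1, mean_cutoff >= 0,
            recurrence_fdr > 0, recurrence_fdr < 1,
            expr_alpha > 0, expr_alpha < 1, de_fdr > 0, de_fdr < 1,
            min_depth <= max_depth)
  cfg <- list(probes = probes, genes = genes, expression = expression,
              vcf = vcf, fasta = fasta, synteny = synteny, meta = meta,
              human_region = human_region, out_dir = out_dir,
              fdr_cna = fdr_cna, min_probes = min_probes,
              mean_cutoff = mean_cutoff, exclude_chroms = exclude_chroms,
              recurrence_fdr = recurrence_fdr, n_perm = n_perm,
              expr_alpha = expr_alpha, de_fdr = de_fdr,
              min_depth = min_depth, max_depth = max_depth,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return The run report (also written as `report.json` in the output
#'   directory), invisibly.  A failing stage writes the report, then stops;
#'   outputs of completed stages are retained.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("crossonc")),
                 seed = config$seed,
                 parameters = config[c("fdr_cna", "min_probes",
                                       "mean_cutoff", "recurrence_fdr",
                                       "n_perm", "expr_alpha", "de_fdr",
                                       "min_depth", "max_depth")],
                 stages = list())
  fail <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(fail)) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(res))
      fail <<- sprintf("stage '%s' failed: %s", name, conditionMessage(res))
      return(NULL)
    }
    report$stages[[name]] <<- c(list(status = "ok"), res$info)
    res$value
  }

  # --- segment + call CNAs -------------------------------------------------
  calls <- run_stage("segment", function() {
    probes <- read_probe_tsv(config$probes)
    calls <- call_cnas(probes, fdr = config$fdr_cna,
                       min_probes = config$min_probes,
                       mean_cutoff = config$mean_cutoff,
                       exclude_chroms = config$exclude_chroms)
    write_seg(calls, file.path(config$out_dir, "calls.seg"))
    summ <- genome_cna_summary(calls)
    jsonlite::write_json(summ$per_sample,
                         file.path(config$out_dir, "cna_summary.json"))
    list(value = calls,
         info = list(n_probes = nrow(probes), n_segments = nrow(calls),
                     n_called = sum(calls$call != "neutral")))
  })

  # --- gene-level CNA + recurrence ----------------------------------------
  recurrence <- run_stage("gene_cna", function() {
    genes <- read_bed(config$genes)
    gc <- assign_gene_status(calls, genes)
    rec <- recurrence_test(gc, n_perm = config$n_perm,
                           fdr = config$recurrence_fdr,
                           seed = config$seed + 1L)
    write.table(rec, file.path(config$out_dir, "gene_recurrence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st <- data.frame(gene_id = rownames(gc$status), gc$status,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(st, file.path(config$out_dir, "gene_cna_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(gc = gc, rec = rec),
         info = list(n_genes = nrow(genes),
                     n_recurrent_amp = sum(rec$recurrent_amp),
                     n_recurrent_del = sum(rec$recurrent_del)))
  })

  # --- expression integration ---------------------------------------------
  run_stage("integrate", function() {
    if (is.null(config$expression)) {
      return(list(value = NULL, info = list(note = "no expression input")))
    }
    mat <- filter_expressed(read_expression_tsv(config$expression))
    ec <- classify_expression(mat, recurrence$gc, alpha = config$expr_alpha)
    write.table(ec, file.path(config$out_dir, "expression_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ct <- concordance_table(ec, recurrence$gc)
    write.table(data.frame(level = rownames(ct), ct, check.names = FALSE),
                file.path(config$out_dir, "concordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    info <- list(n_genes_expressed = nrow(mat),
                 n_calls = sum(ec$level %in% c("low", "normal", "high")))
    if (!is.null(config$meta)) {
      meta <- read_sample_meta(config$meta)
      tum <- intersect(meta$sample_id[meta$role == "tumor"], colnames(mat))
      nor <- intersect(meta$sample_id[meta$role == "normal"], colnames(mat))
      if (length(tum) >= 2 && length(nor) >= 2) {
        de <- differential_expression_ttest(mat, tum, nor,
                                            fdr = config$de_fdr)
        write.table(de, file.path(config$out_dir,
                                  "differential_expression.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        info$n_de_significant <- sum(de$significant)
      }
    }
    list(value = ec, info = info)
  })

  # --- mutation spectrum ---------------------------------------------------
  run_stage("spectrum", function() {
    if (is.null(config$vcf)) {
      return(list(value = NULL, info = list(note = "no variant input")))
    }
    recs <- read_vcf(config$vcf, fasta = config$fasta)
    recs <- filter_by_coverage(recs, config$min_depth, config$max_depth)
    recs <- annotate_context(recs)
    sp <- mutation_spectrum(recs)
    write.table(sp, file.path(config$out_dir, "spectrum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    info <- list(n_records = nrow(recs), n_samples = nrow(sp))
    if (!is.null(config$meta)) {
      meta <- read_sample_meta(config$meta)
      pos <- recs[recs$sample_id %in%
                    meta$sample_id[meta$virus_status == "positive"], ]
      neg <- recs[recs$sample_id %in%
                    meta$sample_id[meta$virus_status == "negative"], ]
      if (nrow(pos) && nrow(neg)) {
        cmp <- compare_cpg_transversions(pos, neg)
        jsonlite::write_json(
          list(table = as.data.frame(cmp$table),
               fractions = cmp$fractions, odds_ratio = cmp$odds_ratio,
               p_value = cmp$p_value),
          file.path(config$out_dir, "cpg_comparison.json"),
          auto_unbox = TRUE, digits = NA)
        info$cpg_p_value <- cmp$p_value
      }
    }
    list(value = sp, info = info)
  })

  # --- driver-passenger discrimination ------------------------------------
  run_stage("discriminate", function() {
    if (is.null(config$synteny) || is.null(config$human_region)) {
      return(list(value = NULL, info = list(note = "no synteny input")))
    }
    map <- read_synteny_tsv(config$synteny)
    hr <- config$human_region
    pr <- project_region(hr$chrom, hr$start, hr$end, map, from = "human")
    hg <- data.frame(gene_id = character(), amplified = logical())
    dp <- discriminate_drivers(recurrence$rec, hg, pr$regions,
                               fdr = config$recurrence_fdr)
    jsonlite::write_json(
      list(status = dp$status, p_value = dp$p_value,
           odds_ratio = dp$odds_ratio, per_region = dp$per_region,
           dcg_ids = dp$dcg_ids, pcg_ids = dp$pcg_ids,
           deleted_ids = dp$deleted_ids),
      file.path(config$out_dir, "driver_passenger.json"),
      auto_unbox = TRUE, digits = NA)
    list(value = dp, info = list(n_regions = nrow(pr$regions),
                                 n_dcg = length(dp$dcg_ids),
                                 n_pcg = length(dp$pcg_ids),
                                 p_value = dp$p_value))
  })

  report$status <- if (is.null(fail)) "ok" else "failed"
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(fail)) stop(fail, call. = FALSE)
  invisible(report)
}
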