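# Readers and writers for every on-disk format the pipeline touches.
#
# Conventions: internal coordinates are 0-based half-open everywhere.
# BED is 0-based half-open on disk, VCF and SEG are 1-based; conversions
# happen only here, at the file boundary.  Gzipped files are accepted by all
# readers (R connections decompress transparently).

#' Read a probe-level log2-ratio table
#'
#' Tab-delimited with columns `chrom`, `pos`, then one numeric column per
#' sample.  Probes are returned sorted by (chrom, pos); duplicate positions
#' within a chromosome are an error.
#'
#' @param path File path (optionally gzipped).
#' @return `data.frame` with chrom, pos, and one column per sample.
#' @export
read_probe_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(df, c("chrom", "pos"), basename(path))
  if (ncol(df) < 3) stop("probe table has no sample columns: ", path)
  for (cn in setdiff(names(df), c("chrom", "pos"))) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("non-numeric log2 ratio in column '%s' (data line %d)",
                   cn, bad))
    }
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "pos")])
  if (any(dup)) {
    stop(sprintf("duplicate probe position %s:%d in %s",
                 df$chrom[which(dup)[1]], df$pos[which(dup)[1]], path))
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_probe_tsv
#' @param probes Probe table as returned by [read_probe_tsv()].
#' @export
write_probe_tsv <- function(probes, path) {
  stopifnot_cols(probes, c("chrom", "pos"), "probe table")
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read segment calls in the IGV SEG dialect
#'
#' On disk: columns Sample, Chromosome, Start, End, Num_Probes, Segment_Mean
#' with 1-based inclusive coordinates.  Internally segments are 0-based
#' half-open.
#'
#' @param calls Segment table with sample_id, chrom, start, end, probe_count,
#'   mean_log2 (and optionally p_value, q_value, call).
#' @param path Output path.
#' @export
write_seg <- function(calls, path) {
  stopifnot_cols(calls, c("sample_id", "chrom", "start", "end",
                          "probe_count", "mean_log2"), "segment table")
  sp <- split(calls, paste(calls$sample_id, chrom_key(calls$chrom)))
  for (d in sp) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping segments within one sample; refusing to write SEG")
    }
  }
  out <- data.frame(Sample = calls$sample_id, Chromosome = calls$chrom,
                    Start = calls$start + 1, End = calls$end,
                    Num_Probes = calls$probe_count,
                    Segment_Mean = calls$mean_log2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("Sample", "Chromosome", "Start", "End",
                       "Num_Probes", "Segment_Mean"), basename(path))
  data.frame(sample_id = df$Sample, chrom = df$Chromosome,
             start = df$Start - 1, end = df$End,
             probe_count = df$Num_Probes, mean_log2 = df$Segment_Mean,
             stringsAsFactors = FALSE)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open on disk, which is also the internal convention.
#'
#' @param path BED file path.
#' @return `data.frame` gene_id, chrom, start, end, strand (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else
    sprintf("feature_%d", seq_along(gr))
  data.frame(gene_id = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param genes Gene table (gene_id, chrom, start, end, strand), 0-based
#'   half-open.
#' @export
write_bed <- function(genes, path) {
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  strand <- genes$strand %||% "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1, genes$end),
    strand = strand, name = genes$gene_id, score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read substitution records from a VCF
#'
#' Multi-allelic rows are split into one record per ALT allele.  Indels and
#' multi-nucleotide records are skipped (a message reports the count): the
#' downstream analyses are substitution-only.  One record is emitted per
#' (site, carrier sample); a sample carries a variant when its genotype
#' contains the alternate allele.  Flanking reference bases are looked up in
#' `fasta` when provided, otherwise set to `"N"`.
#'
#' @param path VCF (v4.x) file, optionally gzipped.
#' @param fasta Optional FASTA path or [Biostrings::DNAStringSet] supplying
#'   flanking context.
#' @return Variant `data.frame`: sample_id, chrom, pos (0-based), ref, alt,
#'   depth, five_prime, three_prime.
#' @export
read_vcf <- function(path, fasta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), five_prime = character(),
                      three_prime = character(), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  recs <- list(); n_skipped <- 0
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- fix$REF[i]
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !(alt %in% c("A", "C", "G", "T"))) {
        n_skipped <- n_skipped + 1
        next
      }
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g)) next
        if (!grepl(as.character(ai), g, fixed = TRUE)) next
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = s, chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]) - 1L, ref = ref, alt = alt,
          depth = as.integer(dp[i, s]), stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d non-substitution allele(s) (indel/MNV)",
                    n_skipped))
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  out <- add_flanks(out, fasta)
  rownames(out) <- NULL
  out
}

add_flanks <- function(records, fasta) {
  if (is.null(fasta)) {
    records$five_prime <- records$five_prime %||% "N"
    records$three_prime <- records$three_prime %||% "N"
    return(records)
  }
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  key <- chrom_key(records$chrom)
  skey <- chrom_key(names(seqs))
  idx <- match(key, skey)
  if (anyNA(idx)) stop("chromosome missing from FASTA: ",
                       records$chrom[which(is.na(idx))[1]])
  five <- character(nrow(records)); three <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- seqs[[idx[i]]]
    p1 <- records$pos[i] + 1L  # 1-based site
    rb <- as.character(Biostrings::subseq(s, p1, p1))
    if (rb != records$ref[i]) {
      stop(sprintf("REF mismatch at %s:%d (VCF %s, FASTA %s)",
                   records$chrom[i], p1, records$ref[i], rb))
    }
    five[i] <- if (p1 > 1)
      as.character(Biostrings::subseq(s, p1 - 1, p1 - 1)) else "N"
    three[i] <- if (p1 < length(s))
      as.character(Biostrings::subseq(s, p1 + 1, p1 + 1)) else "N"
  }
  records$five_prime <- five
  records$three_prime <- three
  records
}

#' Write substitution records as VCF v4.2
#'
#' Records sharing (chrom, pos, ref, alt) across samples are merged into one
#' row; per-sample GT and DP go in the genotype columns.
#'
#' @param records Variant table (see [read_vcf()] for columns).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @export
write_vcf <- function(records, path, contigs = NULL) {
  stopifnot_cols(records, c("sample_id", "chrom", "pos", "ref", "alt",
                            "depth"), "variant table")
  samples <- sort(unique(records$sample_id))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=crossonc",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  ord <- order(records$chrom, records$pos)
  ukey <- unique(key[ord])
  rows <- character(length(ukey))
  for (i in seq_along(ukey)) {
    rr <- records[key == ukey[i], , drop = FALSE]
    cells <- rep("./.:.", length(samples))
    names(cells) <- samples
    cells[rr$sample_id] <- sprintf("0/1:%d", rr$depth)
    rows[i] <- paste(c(rr$chrom[1], rr$pos[1] + 1L, ".", rr$ref[1],
                       rr$alt[1], ".", "PASS", ".", "GT:DP", cells),
                     collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write a synteny block map
#'
#' Tab-delimited with columns human_chrom, h_start, h_end, dog_chrom,
#' d_start, d_end, orientation; coordinates 0-based half-open on disk and in
#' memory.  Every block must have equal human and dog lengths and human
#' blocks must not overlap.
#'
#' @param path File path.
#' @return Block `data.frame`.
#' @export
read_synteny_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_synteny(df)
}

#' @rdname read_synteny_tsv
#' @param blocks Block table.
#' @export
write_synteny_tsv <- function(blocks, path) {
  validate_synteny(blocks)
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_synteny <- function(df) {
  stopifnot_cols(df, c("human_chrom", "h_start", "h_end", "dog_chrom",
                       "d_start", "d_end", "orientation"), "synteny map")
  if (!all(df$orientation %in% c("+", "-"))) {
    stop("synteny orientation must be '+' or '-'")
  }
  if (any(df$h_end <= df$h_start) || any(df$d_end <= df$d_start)) {
    stop("synteny blocks must be non-empty intervals")
  }
  if (any((df$h_end - df$h_start) != (df$d_end - df$d_start))) {
    stop("synteny block human/dog lengths differ (no within-block gaps allowed)")
  }
  sp <- split(df, chrom_key(df$human_chrom))
  for (d in sp) {
    d <- d[order(d$h_start), ]
    if (nrow(d) > 1 && any(d$h_start[-1] < d$h_end[-nrow(d)])) {
      stop("human synteny intervals overlap")
    }
  }
  df
}

#' Read / write a gene-by-sample expression matrix
#'
#' Tab-delimited: first column `gene_id`, remaining columns numeric
#' (FPKM-scale) per sample.
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(df, "gene_id", basename(path))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_expression_tsv
#' @param mat Numeric matrix, genes x samples.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited with columns sample_id, role (`tumor`/`normal`), site,
#' virus_status (`positive`/`negative`/`unknown`), case_id.
#'
#' @param path File path.
#' @return `data.frame` of validated metadata.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample_id", "role", "site", "virus_status",
                       "case_id"), basename(path))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  if (!all(df$role %in% c("tumor", "normal"))) {
    stop("role must be 'tumor' or 'normal'")
  }
  if (!all(df$virus_status %in% c("positive", "negative", "unknown"))) {
    stop("virus_status must be positive/negative/unknown")
  }
  df
}
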