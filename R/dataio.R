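#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file with a `GT` FORMAT field and optional `GQ`
#' (Phred-scaled genotype quality), `DS` (alt-allele dosage) and `DP` (read
#' depth) FORMAT fields, plus an optional `DR2` INFO field carrying the
#' imputation dosage r-squared (Beagle dialect). Multi-allelic records are
#' skipped with a message; missing GQ becomes 0 and missing DS is derived
#' from the hard call. MAF and call rate are computed from the calls when
#' not supplied in INFO.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no records")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  calls <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                  dimnames = dimnames(gt_raw))
  norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  calls[norm %in% c("0/0")] <- 0L
  calls[norm %in% c("0/1", "1/0")] <- 1L
  calls[norm %in% c("1/1")] <- 2L

  fmt <- strsplit(vcf@gt[, 1], ":", fixed = TRUE)[[1]]
  grab <- function(el) {
    if (!el %in% fmt) return(NULL)
    m <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
    m
  }
  gq <- grab("GQ")
  if (is.null(gq)) gq <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  gq[is.na(gq)] <- 0
  dosage <- grab("DS")
  if (is.null(dosage)) dosage <- calls + 0.0 else {
    na <- is.na(dosage) & !is.na(calls)
    dosage[na] <- calls[na]
  }
  depth <- grab("DP")
  if (!is.null(depth)) storage.mode(depth) <- "integer"

  dr2 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "DR2")))
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    dr2 = dr2,
    stringsAsFactors = FALSE
  )
  genotype_table(variants, calls, gq = gq, dosage = dosage, depth = depth)
}

#' Write a genotype table to VCF
#'
#' Emits a minimal VCF 4.2 file with `DR2` and `AF` INFO fields and a
#' `GT:GQ:DS` (plus `DP` when depths are present) FORMAT.
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  v <- gt$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Estimated imputation dosage r-squared\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Phred-scaled genotype quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alt-allele dosage\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t")
  ), con)
  gtc <- c("0/0", "0/1", "1/1")
  has_dp <- !is.null(gt$depth)
  fmt <- if (has_dp) "GT:GQ:DS:DP" else "GT:GQ:DS"
  af <- ifelse(is.na(v$maf), ".", format(v$maf, digits = 6))
  dr2 <- ifelse(is.na(v$dr2), ".", format(v$dr2, digits = 6))
  lines <- vapply(seq_len(nrow(v)), function(i) {
    cell <- vapply(seq_along(gt$samples), function(j) {
      g <- gt$calls[i, j]
      gs <- if (is.na(g)) "./." else gtc[g + 1L]
      ds <- if (is.na(gt$dosage[i, j])) "." else format(round(gt$dosage[i, j], 4))
      base <- paste(gs, format(round(gt$gq[i, j], 2)), ds, sep = ":")
      if (has_dp) paste0(base, ":", gt$depth[i, j]) else base
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref_allele[i],
            v$alt_allele[i], ".", "PASS",
            paste0("DR2=", dr2[i], ";AF=", af[i]), fmt, cell),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a gene-level expression matrix from TSV
#'
#' Expects a header row; the first column is `gene_id`, followed by gene
#' annotation columns (`chrom`, `start`, `end`, `gc_fraction`) when no
#' companion annotation is supplied, then one column per sample.
#'
#' @param path TSV path.
#' @param annotation optional data.frame of gene annotation (`gene_id`,
#'   `chrom`, `start`, `end`, `gc_fraction`); every gene in it must be
#'   present in the file.
#' @param counts logical; when TRUE values are validated as raw counts.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation = NULL, counts = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann_cols <- intersect(c("chrom", "start", "end", "gc_fraction"), names(df))
  if (is.null(annotation)) {
    if (!all(c("chrom", "start", "end") %in% ann_cols))
      stop("no annotation supplied and file lacks chrom/start/end columns")
    genes <- df[, c("gene_id", ann_cols)]
  } else {
    missing_genes <- setdiff(annotation$gene_id, df$gene_id)
    if (length(missing_genes))
      stop("genes in annotation absent from expression file: ",
           paste(missing_genes, collapse = ", "))
    df <- df[match(annotation$gene_id, df$gene_id), , drop = FALSE]
    genes <- annotation
  }
  sample_cols <- setdiff(names(df), c("gene_id", ann_cols))
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  if (counts && (any(values < 0) || any(values != round(values))))
    stop("raw counts requested but file contains non-integer or negative values")
  expression_matrix(genes, values, counts = counts)
}

#' Write an expression matrix to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- cbind(expr$genes[, intersect(c("gene_id", "chrom", "start", "end",
                                       "gc_fraction"), names(expr$genes))],
              as.data.frame(expr$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# BED is 0-based half-open; internal coordinates are 1-based inclusive.
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
}

#' Read per-sample allelic read counts, flagging excluded regions
#'
#' Reads a TSV with columns `variant_id`, `chrom`, `pos` (1-based),
#' `sample_id`, `ref_count`, `alt_count`. Each row is flagged
#' `in_excluded_region` when its position falls inside any interval of the
#' exclusion BED files (RNA-editing sites, splice-junction neighbourhoods,
#' repeat regions, ...). A mappability BED with scores in column 5 attaches
#' a per-site mappability; sites not covered by the track (or when no track
#' is given) default to 1.0.
#'
#' @param path allelic-count TSV.
#' @param exclusions character vector of BED paths (0-based half-open).
#' @param mappability optional BED path with a score column.
#' @return An `allelic_count_table` data.frame.
#' @export
read_allelic_counts <- function(path, exclusions = character(),
                                mappability = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "sample_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allelic count file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("variant_id", "sample_id")]))
    stop("duplicate (variant, sample) rows in allelic count file")
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stop("negative allelic counts")
  sites <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  df$in_excluded_region <- FALSE
  for (bedpath in exclusions) {
    gr <- bed_to_granges(read_bed(bedpath))
    hit <- IRanges::overlapsAny(sites, gr)
    df$in_excluded_region <- df$in_excluded_region | hit
  }
  df$mappability <- 1.0
  if (!is.null(mappability)) {
    bed <- read_bed(mappability)
    if (is.null(bed$score)) stop("mappability BED lacks a score column")
    gr <- bed_to_granges(bed)
    ov <- GenomicRanges::findOverlaps(sites, gr, select = "first")
    covered <- !is.na(ov)
    df$mappability[covered] <- bed$score[ov[covered]]
  }
  class(df) <- c("allelic_count_table", class(df))
  df
}

#' Write an allelic count table to TSV
#'
#' @param counts an allelic count table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with the [sample_sheet()] columns.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(df$is_reference_set))
    df$is_reference_set <- as.logical(df$is_reference_set)
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#'
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table to TSV with deterministic order
#'
#' Columns keep their given order; rows are stably sorted by whichever of
#' `chrom`, `pos`, `gene_id` (then `variant_id`, `sample_id`) are present,
#' so two runs on the same input produce byte-identical files.
#'
#' @param results a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  keys <- intersect(c("chrom", "pos", "gene_id", "variant_id", "sample_id"),
                    names(df))
  if (length(keys) && nrow(df) > 1)
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
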