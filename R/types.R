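#' Construct a genotype table
#'
#' Container for per-sample, per-variant genotype information as produced by
#' a variant caller plus imputation: hard calls, Phred-scaled genotype
#' qualities (GQ), expected alternative-allele dosages, and optional read
#' depths, together with per-variant metadata (imputation dosage r-squared,
#' minor allele frequency, call rate).
#'
#' Hard calls are coded 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternative) and `NA` (missing). All matrices are
#' variants x samples with matching dimnames.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref_allele`, `alt_allele`, and optionally `dr2`, `maf`,
#'   `call_rate`. `maf` and `call_rate` are computed from the calls when
#'   absent.
#' @param calls integer matrix of hard calls (0/1/2/NA), variants x samples.
#' @param gq numeric matrix of Phred-scaled genotype qualities (>= 0), or
#'   NULL for all-zero.
#' @param dosage numeric matrix of expected alt-allele counts in \[0, 2\], or
#'   NULL to derive from hard calls.
#' @param depth optional integer matrix of per-sample read depths at each
#'   site (used by heterozygosity QC).
#' @return An object of class `genotype_table`: a list with elements
#'   `variants`, `samples`, `calls`, `gq`, `dosage`, `depth`.
#' @export
genotype_table <- function(variants, calls, gq = NULL, dosage = NULL,
                           depth = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(calls))
  need <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants missing columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) != nrow(calls))
    stop("variants and calls disagree on the number of variants")
  if (any(variants$pos <= 0)) stop("positions must be strictly positive")
  samples <- colnames(calls)
  if (is.null(samples)) stop("calls must have sample column names")
  if (is.null(gq)) {
    gq <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  if (is.null(dosage)) {
    dosage <- calls + 0.0
  }
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  if (any(gq < 0, na.rm = TRUE)) stop("gq must be >= 0")
  rownames(calls) <- rownames(gq) <- rownames(dosage) <- variants$variant_id
  if (!is.null(depth)) rownames(depth) <- variants$variant_id
  if (is.null(variants$maf) || is.null(variants$call_rate)) {
    cr <- rowMeans(!is.na(calls))
    af <- rowSums(calls, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(calls)), 1L))
    if (is.null(variants$maf)) variants$maf <- pmin(af, 1 - af)
    if (is.null(variants$call_rate)) variants$call_rate <- cr
  }
  if (is.null(variants$dr2)) variants$dr2 <- NA_real_
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("maf outside [0, 0.5]")
  structure(
    list(variants = variants, samples = samples, calls = calls,
         gq = gq, dosage = dosage, depth = depth),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Subset a genotype table by variant and/or sample
#'
#' @param gt a [genotype_table()].
#' @param variants logical/integer/character index of variants to keep.
#' @param samples logical/integer/character index of samples to keep.
#' @return A `genotype_table` restricted to the selection. Per-variant `maf`
#'   and `call_rate` are kept as-is (they describe the full cohort).
#' @export
subset_genotypes <- function(gt, variants = NULL, samples = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  vi <- if (is.null(variants)) seq_len(nrow(gt$variants)) else variants
  si <- if (is.null(samples)) seq_along(gt$samples) else samples
  if (is.character(vi)) vi <- match(vi, gt$variants$variant_id)
  if (is.character(si)) si <- match(si, gt$samples)
  out <- gt
  out$variants <- gt$variants[vi, , drop = FALSE]
  out$calls <- gt$calls[vi, si, drop = FALSE]
  out$gq <- gt$gq[vi, si, drop = FALSE]
  out$dosage <- gt$dosage[vi, si, drop = FALSE]
  if (!is.null(gt$depth)) out$depth <- gt$depth[vi, si, drop = FALSE]
  out$samples <- gt$samples[si]
  out
}

#' Construct an expression matrix
#'
#' Genes x samples matrix of raw counts or normalized values, with gene
#' coordinates and GC content. The gene center used for cis-window
#' calculations is `floor((start + end) / 2)`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `gc_fraction` in \[0, 1\].
#' @param values numeric matrix genes x samples; raw counts must be
#'   non-negative integers.
#' @param counts logical; TRUE when `values` are raw counts.
#' @param total_mapped_reads optional per-sample totals; column sums of the
#'   count matrix when absent.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(genes, values, counts = TRUE,
                              total_mapped_reads = NULL) {
  stopifnot(is.data.frame(genes), is.matrix(values))
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes missing columns: ", paste(miss, collapse = ", "))
  if (nrow(genes) != nrow(values))
    stop("genes and values disagree on the number of genes")
  if (is.null(colnames(values))) stop("values must have sample column names")
  if (counts) {
    if (any(values < 0) || any(values != round(values)))
      stop("raw counts must be non-negative integers")
    if (is.null(total_mapped_reads)) total_mapped_reads <- colSums(values)
  }
  if (is.null(genes$gc_fraction)) genes$gc_fraction <- NA_real_
  rownames(values) <- genes$gene_id
  structure(
    list(genes = genes, values = values, counts = counts,
         total_mapped_reads = total_mapped_reads),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$counts) "raw counts" else "normalized"))
  invisible(x)
}

#' Gene centers of an expression matrix
#'
#' @param expr an [expression_matrix()].
#' @return Integer vector `floor((start + end) / 2)` per gene.
#' @export
gene_centers <- function(expr) {
  as.integer(floor((expr$genes$start + expr$genes$end) / 2))
}

#' Construct a sample sheet
#'
#' @param df data.frame with columns `sample_id`, `study_id`, `population`,
#'   `tissue`; optional `is_reference_set` (logical priority flag),
#'   `annotated_sex` (male/female/unknown), `n_expressed_genes`.
#' @return The validated data.frame with class `sample_sheet` prepended.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "study_id", "population", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_ids must be unique")
  if (is.null(df$is_reference_set)) df$is_reference_set <- FALSE
  if (is.null(df$annotated_sex)) df$annotated_sex <- "unknown"
  if (is.null(df$n_expressed_genes)) df$n_expressed_genes <- NA_integer_
  bad <- setdiff(unique(df$annotated_sex), c("male", "female", "unknown"))
  if (length(bad)) stop("annotated_sex must be male/female/unknown")
  class(df) <- c("sample_sheet", class(df))
  df
}
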