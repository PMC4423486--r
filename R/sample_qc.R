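#' Principal component analysis of expression samples
#'
#' PCA over the sample covariance structure of a (quantile-normalized,
#' log2-transformed) expression matrix: samples are the observations, genes
#' the variables. Constant gene rows carry no covariance information and are
#' dropped with a message. Components are ordered by explained variance;
#' scores are reproducible up to sign.
#'
#' @param expr an [expression_matrix()] of normalized values.
#' @param n_components number of components to return (truncated to
#'   `min(n_samples - 1, n_genes)`).
#' @return List with `scores` (samples x components), `loadings` (genes x
#'   components), `var_explained` (proportion per component) and
#'   `n_genes_dropped`.
#' @export
expression_pca <- function(expr, n_components = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (ncol(v) < 3) stop("need at least 3 samples for a PCA")
  sds <- apply(v, 1, stats::sd)
  keep <- sds > 0
  if (any(!keep)) message(sum(!keep), " constant gene row(s) dropped before PCA")
  v <- v[keep, , drop = FALSE]
  k <- min(n_components, ncol(v) - 1L, nrow(v))
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
    n_genes_dropped = sum(!keep)
  )
}

#' Flag expression outliers on a principal component
#'
#' Samples whose score on one chosen component deviates strongly are flagged,
#' either by absolute robust z-score (score minus median, over the MAD) or by
#' a raw absolute threshold.
#'
#' @param scores score matrix from [expression_pca()].
#' @param component column index of the component to screen (default 1, the
#'   component on which gross technical outliers typically separate).
#' @param method `"zscore"` (robust z, default) or `"threshold"` (raw |score|).
#' @param cutoff flag when the statistic exceeds this value (default 4 MADs).
#' @return Character vector of flagged sample ids.
#' @export
flag_expression_outliers <- function(scores, component = 1,
                                     method = c("zscore", "threshold"),
                                     cutoff = 4) {
  method <- match.arg(method)
  if (is.null(dim(scores)) || nrow(scores) == 0) stop("empty score matrix")
  x <- scores[, component]
  stat <- if (method == "zscore") {
    m <- stats::mad(x)
    if (m == 0) rep(0, length(x)) else abs(x - stats::median(x)) / m
  } else abs(x)
  rownames(scores)[stat > cutoff]
}

#' Per-sample heterozygosity rate from hard genotype calls
#'
#' The fraction of non-missing calls that are heterozygous, restricted to
#' sites with MAF at or above `min_maf` and per-sample read coverage of at
#' least `min_depth` reads (non-imputed calls are assumed). Samples with
#' fewer than `min_sites` qualifying sites get `NA` (unknown) — the estimate
#' would be too noisy to act on.
#'
#' @param gt a [genotype_table()] with a `depth` matrix.
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_depth minimum per-sample read coverage at the site (default 10).
#' @param min_sites minimum qualifying sites for a usable estimate
#'   (default 50; binomial SE below ~0.07).
#' @return data.frame with `sample_id`, `het_rate`, `n_snps_used`.
#' @export
heterozygosity_rate <- function(gt, min_maf = 0.05, min_depth = 10,
                                min_sites = 50) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$depth)) stop("genotype table carries no read depths")
  vkeep <- gt$variants$maf >= min_maf
  calls <- gt$calls[vkeep, , drop = FALSE]
  depth <- gt$depth[vkeep, , drop = FALSE]
  ok <- !is.na(calls) & depth >= min_depth
  n_used <- colSums(ok)
  if (all(n_used == 0)) stop("no qualifying sites for any sample")
  n_het <- colSums(calls == 1L & ok, na.rm = TRUE)
  rate <- ifelse(n_used >= min_sites, n_het / pmax(n_used, 1L), NA_real_)
  data.frame(sample_id = gt$samples, het_rate = rate,
             n_snps_used = as.integer(n_used),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag samples with abnormal heterozygosity
#'
#' Rates strictly below `low` suggest chromosomal aberrations, uniparental
#' disomy or strong inbreeding; rates strictly above `high` suggest
#' contaminated or pooled samples. Both bounds are exclusive. Unknown (`NA`)
#' rates are never flagged.
#'
#' @param rates data.frame from [heterozygosity_rate()].
#' @param low,high exclusive bounds (defaults 0.2 and 0.4).
#' @return `rates` with a `flag` column in `{none, low_het, high_het}`.
#' @export
filter_heterozygosity <- function(rates, low = 0.2, high = 0.4) {
  if (low >= high) stop("low bound must be below high bound")
  flag <- rep("none", nrow(rates))
  flag[!is.na(rates$het_rate) & rates$het_rate < low] <- "low_het"
  flag[!is.na(rates$het_rate) & rates$het_rate > high] <- "high_het"
  rates$flag <- flag
  rates
}

#' Predict sample sex from XIST and chromosome-Y expression
#'
#' Splits samples by 2-means on the (XIST, mean chrY expression) plane —
#' females show high XIST and near-zero Y expression, males the opposite —
#' and compares the prediction with the annotated sex where available.
#' Initial centers are the samples with the highest and lowest XIST value,
#' making the clustering deterministic.
#'
#' @param expr an [expression_matrix()] of normalized values.
#' @param sheet a [sample_sheet()].
#' @param xist_gene gene id of XIST (default "XIST").
#' @param chry_genes character vector of Y-chromosome gene ids; by default
#'   every gene annotated on chromosome "Y"/"chrY".
#' @return data.frame with `sample_id`, `sex_predicted`, `annotated_sex`,
#'   `sex_mismatch`.
#' @export
sex_check <- function(expr, sheet, xist_gene = "XIST", chry_genes = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  ids <- colnames(expr$values)
  ann <- sheet$annotated_sex[match(ids, sheet$sample_id)]
  unknown <- data.frame(sample_id = ids, sex_predicted = "unknown",
                        annotated_sex = ann, sex_mismatch = FALSE,
                        stringsAsFactors = FALSE)
  if (is.null(chry_genes))
    chry_genes <- expr$genes$gene_id[expr$genes$chrom %in% c("Y", "chrY")]
  if (!xist_gene %in% expr$genes$gene_id || !length(intersect(chry_genes, expr$genes$gene_id))) {
    warning("XIST or chrY genes absent; sex predictions unknown")
    return(unknown)
  }
  xist <- expr$values[match(xist_gene, expr$genes$gene_id), ]
  ymean <- colMeans(expr$values[match(intersect(chry_genes, expr$genes$gene_id),
                                      expr$genes$gene_id), , drop = FALSE])
  f <- scale(cbind(xist, ymean))
  if (any(!is.finite(f))) f[!is.finite(f)] <- 0
  centers <- f[c(which.max(xist), which.min(xist)), , drop = FALSE]
  if (all(centers[1, ] == centers[2, ])) return(unknown)
  km <- stats::kmeans(f, centers = centers)
  fem_cluster <- which.max(tapply(xist, km$cluster, mean))
  pred <- ifelse(km$cluster == fem_cluster, "female", "male")
  data.frame(sample_id = ids, sex_predicted = pred, annotated_sex = ann,
             sex_mismatch = ann != "unknown" & !is.na(ann) & pred != ann,
             stringsAsFactors = FALSE)
}

#' Run the full sample-QC stage
#'
#' Combines expression-PCA outlier flagging, heterozygosity-rate filtering
#' and the sex-annotation check into one per-sample report.
#'
#' @param expr_norm normalized [expression_matrix()] (quantile + log2).
#' @param gt a [genotype_table()] with depths.
#' @param sheet a [sample_sheet()].
#' @param pc_component,pc_cutoff outlier screen settings
#'   (see [flag_expression_outliers()]).
#' @param stratify_outliers logical; when TRUE (default) the robust z-score
#'   for the outlier screen is computed within each study, since studies
#'   (and their tissues) legitimately differ in expression and a global
#'   screen would flag whole studies on a component that separates them.
#' @param het_low,het_high heterozygosity bounds (see
#'   [filter_heterozygosity()]).
#' @param min_maf,min_depth,min_sites see [heterozygosity_rate()].
#' @return data.frame with one row per sample: PC scores, het rate, predicted
#'   sex, and a comma-joined `flags` column drawn from
#'   `{expression_outlier, low_het, high_het, sex_mismatch}`.
#' @export
run_sample_qc <- function(expr_norm, gt, sheet, pc_component = 1,
                          pc_cutoff = 4, stratify_outliers = TRUE,
                          het_low = 0.2, het_high = 0.4,
                          min_maf = 0.05, min_depth = 10, min_sites = 50) {
  # the outlier screen runs on autosomes only: sex-chromosome genes split
  # samples by sex, which is biology, not a quality problem
  auto <- !(expr_norm$genes$chrom %in% c("X", "Y", "chrX", "chrY", "MT", "chrM"))
  expr_auto <- expr_norm
  expr_auto$genes <- expr_norm$genes[auto, , drop = FALSE]
  expr_auto$values <- expr_norm$values[auto, , drop = FALSE]
  pca <- expression_pca(expr_auto, n_components = 2)
  if (stratify_outliers) {
    out <- unlist(lapply(unique(sheet$study_id), function(st) {
      members <- intersect(sheet$sample_id[sheet$study_id == st],
                           rownames(pca$scores))
      if (length(members) < 3) return(character(0))
      flag_expression_outliers(pca$scores[members, , drop = FALSE],
                               component = pc_component, cutoff = pc_cutoff)
    }))
  } else {
    out <- flag_expression_outliers(pca$scores, component = pc_component,
                                    cutoff = pc_cutoff)
  }
  het <- filter_heterozygosity(
    heterozygosity_rate(gt, min_maf = min_maf, min_depth = min_depth,
                        min_sites = min_sites),
    low = het_low, high = het_high)
  sex <- sex_check(expr_norm, sheet)
  ids <- sheet$sample_id
  flags <- vapply(ids, function(s) {
    fl <- character(0)
    if (s %in% out) fl <- c(fl, "expression_outlier")
    hf <- het$flag[match(s, het$sample_id)]
    if (!is.na(hf) && hf != "none") fl <- c(fl, hf)
    if (isTRUE(sex$sex_mismatch[match(s, sex$sample_id)]))
      fl <- c(fl, "sex_mismatch")
    paste(fl, collapse = ",")
  }, character(1))
  data.frame(
    sample_id = ids,
    pc1 = pca$scores[match(ids, rownames(pca$scores)), 1],
    pc2 = pca$scores[match(ids, rownames(pca$scores)), 2],
    het_rate = het$het_rate[match(ids, het$sample_id)],
    n_snps_used = het$n_snps_used[match(ids, het$sample_id)],
    sex_predicted = sex$sex_predicted[match(ids, sex$sample_id)],
    flags = unname(flags),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
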