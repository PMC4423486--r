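#' Enumerate cis variant-gene pairs
#'
#' All (variant, gene) pairs on the same chromosome with the variant within
#' `window_bp` of the gene center (`floor((start + end) / 2)`), the window
#' boundary inclusive, restricted to variants with imputation dosage
#' r-squared at or above `min_dr2` and MAF at or above `min_maf`.
#'
#' @param gt a [genotype_table()].
#' @param expr an [expression_matrix()] (its annotation provides centers).
#' @param window_bp cis window half-width in bp (default 250000).
#' @param min_dr2 inclusive dosage r-squared bound (default 0.8).
#' @param min_maf inclusive MAF bound (default 0.05).
#' @return data.frame `variant_id`, `gene_id`, `distance` (bp).
#' @export
build_cis_pairs <- function(gt, expr, window_bp = 250000, min_dr2 = 0.8,
                            min_maf = 0.05) {
  v <- gt$variants
  vkeep <- which(!is.na(v$dr2) & v$dr2 >= min_dr2 & v$maf >= min_maf)
  centers <- gene_centers(expr)
  g <- expr$genes
  out <- lapply(seq_len(nrow(g)), function(i) {
    j <- vkeep[v$chrom[vkeep] == g$chrom[i]]
    if (!length(j)) return(NULL)
    d <- abs(v$pos[j] - centers[i])
    j <- j[d <= window_bp]
    if (!length(j)) return(NULL)
    data.frame(variant_id = v$variant_id[j], gene_id = g$gene_id[i],
               distance = abs(v$pos[j] - centers[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0)
    stop("no cis pairs within the window after variant filters")
  rownames(out) <- NULL
  out
}

# rank rows and standardize to mean 0, unit sum of squares / (n-1);
# zero-variance rows become NA
row_rank_scale <- function(m) {
  r <- t(apply(m, 1, rank))
  mu <- rowMeans(r)
  ss <- sqrt(rowSums((r - mu)^2) / (ncol(m) - 1))
  out <- (r - mu) / ss
  out[ss == 0, ] <- NA_real_
  out
}

#' Associate dosage with residual expression in one population
#'
#' Spearman rank correlation between alt-allele dosage and residual
#' expression across the given samples, converted to a z-score through the
#' t approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))`, two-sided p
#' from the t distribution, and `z` the standard-normal quantile of that p
#' carrying the sign of rho.
#'
#' @param pairs data.frame from [build_cis_pairs()].
#' @param gt a [genotype_table()].
#' @param resid residual [expression_matrix()] from normalization.
#' @param samples sample ids of one population (must exist in both tables).
#' @return `pairs` with columns `rho`, `z`, `n` added; pairs whose dosage has
#'   zero variance in these samples get `NA` statistics.
#' @export
associate_population <- function(pairs, gt, resid, samples) {
  si_g <- match(samples, gt$samples)
  si_e <- match(samples, colnames(resid$values))
  if (anyNA(si_g) || anyNA(si_e))
    stop("samples missing from genotype or expression table")
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples")
  vi <- match(pairs$variant_id, gt$variants$variant_id)
  gi <- match(pairs$gene_id, resid$genes$gene_id)
  keep <- !is.na(gi)
  zg <- row_rank_scale(gt$dosage[unique(vi), si_g, drop = FALSE])
  ze <- row_rank_scale(resid$values[unique(gi[keep]), si_e, drop = FALSE])
  rho <- rep(NA_real_, nrow(pairs))
  vrow <- match(vi, unique(vi))
  erow <- match(gi, unique(gi[keep]))
  ok <- keep & !is.na(erow)
  rho[ok] <- rowSums(zg[vrow[ok], , drop = FALSE] *
                     ze[erow[ok], , drop = FALSE]) / (n - 1)
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  z <- sign(rho) * stats::qnorm(pmax(p / 2, 1e-300), lower.tail = FALSE)
  pairs$rho <- rho
  pairs$z <- z
  pairs$n <- ifelse(is.na(rho), NA_integer_, n)
  pairs
}

#' Combine population z-scores by sample-size-weighted meta-analysis
#'
#' `meta_z = sum(z_k * sqrt(n_k)) / sqrt(sum(n_k))` over the populations with
#' a defined statistic; two-sided p from the standard normal. With a single
#' population `meta_z` equals its z exactly.
#'
#' @param z matrix of z-scores, pairs x populations (NA where a population
#'   was skipped).
#' @param n matrix of per-population sample sizes, same shape.
#' @return data.frame `meta_z`, `p_value`.
#' @export
meta_analyze <- function(z, n) {
  z <- as.matrix(z); n <- as.matrix(n)
  w <- sqrt(n)
  w[is.na(z)] <- NA
  num <- rowSums(z * w, na.rm = TRUE)
  den <- sqrt(rowSums(n * !is.na(z), na.rm = TRUE))
  meta_z <- ifelse(den > 0, num / den, NA_real_)
  p <- 2 * stats::pnorm(-abs(meta_z))
  data.frame(meta_z = meta_z, p_value = pmax(p, 1e-300))
}

#' Population-stratified cis-eQTL mapping with meta-analysis
#'
#' Runs [associate_population()] per population (populations with fewer than
#' `min_n` samples are excluded from the meta-analysis) and combines the
#' z-scores with [meta_analyze()]. Direction is the sign of `meta_z` with
#' respect to the alt-allele dosage (positive: alt allele increases
#' expression).
#'
#' @param pairs data.frame from [build_cis_pairs()].
#' @param gt a [genotype_table()].
#' @param resid residual [expression_matrix()].
#' @param sheet a [sample_sheet()] (population labels; only samples present
#'   in both tables are used).
#' @param min_n minimum samples for a population to enter the meta
#'   (default 30).
#' @return `pairs` with `meta_z`, `p_value`, `direction` plus per-population
#'   `z_<pop>` and `n_<pop>` columns.
#' @export
map_eqtl <- function(pairs, gt, resid, sheet, min_n = 30) {
  usable <- intersect(gt$samples, colnames(resid$values))
  pops <- split(sheet$sample_id[sheet$sample_id %in% usable],
                sheet$population[sheet$sample_id %in% usable])
  pops <- pops[vapply(pops, length, integer(1)) >= min_n]
  if (!length(pops))
    stop("no population reaches min_n = ", min_n, " samples")
  zmat <- nmat <- matrix(NA_real_, nrow(pairs), length(pops),
                         dimnames = list(NULL, names(pops)))
  for (p in names(pops)) {
    res <- associate_population(pairs, gt, resid, pops[[p]])
    zmat[, p] <- res$z
    nmat[, p] <- res$n
  }
  meta <- meta_analyze(zmat, nmat)
  out <- cbind(pairs, meta)
  out$direction <- ifelse(is.na(out$meta_z), NA_character_,
                          ifelse(out$meta_z > 0, "alt_higher",
                                 ifelse(out$meta_z < 0, "ref_higher", "balanced")))
  colnames(zmat) <- paste0("z_", names(pops))
  colnames(nmat) <- paste0("n_", names(pops))
  cbind(out, zmat, nmat)
}

# per-gene best pair: smallest p, then smallest distance, then variant_id
best_per_gene <- function(res) {
  ord <- order(res$gene_id, res$p_value, res$distance, res$variant_id)
  res <- res[ord, , drop = FALSE]
  res[!duplicated(res$gene_id), , drop = FALSE]
}

# permute expression columns within each study; returns the permuted
# residual matrix (the genotype-to-expression linkage is shuffled, study
# composition preserved)
permute_within_study <- function(resid, sheet) {
  ids <- colnames(resid$values)
  new <- ids
  for (st in unique(sheet$study_id)) {
    members <- intersect(sheet$sample_id[sheet$study_id == st], ids)
    if (length(members) == 1) next
    new[match(members, ids)] <- sample(members)
  }
  out <- resid
  out$values <- resid$values[, match(ids, new), drop = FALSE]
  colnames(out$values) <- ids
  out
}

#' Gene-level permutation FDR for cis-eQTL mapping
#'
#' The observed statistic per gene is its best (smallest) meta-analysis p
#' over its cis variants. The null is built by permuting the
#' expression-to-genotype sample linkage within each study (studies mostly
#' carry one tissue, so this preserves tissue composition) and repeating the
#' whole association + meta-analysis. The FDR at threshold t is the mean
#' permutation count of genes with best p <= t divided by the observed
#' count, clipped to \[0, 1\] and monotonized to be non-decreasing in t.
#'
#' @param pairs data.frame from [build_cis_pairs()].
#' @param gt a [genotype_table()].
#' @param resid residual [expression_matrix()].
#' @param sheet a [sample_sheet()] with `study_id` for every sample.
#' @param n_perm number of permutations (default 10).
#' @param seed RNG seed for the permutations.
#' @param min_n see [map_eqtl()].
#' @return List with `genes` (per-gene `gene_id`, top `variant_id`,
#'   `distance`, `meta_z`, `p_value`, `fdr`, `direction`), `associations`
#'   (all real pair-level results) and `n_perm`.
#' @export
permutation_fdr <- function(pairs, gt, resid, sheet, n_perm = 10, seed = 1,
                            min_n = 30) {
  singles <- table(sheet$study_id)
  if (any(singles == 1))
    warning("study with a single sample: its label cannot be permuted")
  real <- map_eqtl(pairs, gt, resid, sheet, min_n = min_n)
  best <- best_per_gene(real)
  best <- best[!is.na(best$p_value), , drop = FALSE]
  set.seed(seed)
  null_p <- matrix(NA_real_, nrow(best), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- permute_within_study(resid, sheet)
    pres <- map_eqtl(pairs, gt, perm, sheet, min_n = min_n)
    pb <- best_per_gene(pres)
    null_p[, b] <- pb$p_value[match(best$gene_id, pb$gene_id)]
  }
  ord <- order(best$p_value)
  p_sorted <- best$p_value[ord]
  n_real <- seq_along(p_sorted)
  n_null <- vapply(p_sorted, function(t) mean(colSums(null_p <= t, na.rm = TRUE)),
                   numeric(1))
  fdr_sorted <- pmin(1, pmax(0, n_null / n_real))
  fdr_sorted <- cummax(fdr_sorted)
  fdr <- numeric(nrow(best))
  fdr[ord] <- fdr_sorted
  genes <- best[, c("gene_id", "variant_id", "distance", "meta_z",
                    "p_value", "direction")]
  genes$fdr <- fdr
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, associations = real, n_perm = n_perm)
}

#' Replication rate and allelic-direction concordance between two analyses
#'
#' For every gene significant in analysis A (gene-level FDR at or below
#' `fdr_cutoff`), its top variant is looked up in analysis B. The
#' replication rate is the fraction of those genes that are significant in
#' B; direction concordance is the fraction of replicated genes whose
#' meta-z sign matches between A and B at that pair.
#'
#' @param res_a,res_b results from [permutation_fdr()] on a shared pair
#'   space.
#' @param fdr_cutoff significance cutoff (default 0.05).
#' @return List with `n_significant_a`, `n_replicated`,
#'   `replication_rate`, `direction_concordance`.
#' @export
replicate_eqtl <- function(res_a, res_b, fdr_cutoff = 0.05) {
  sig_a <- res_a$genes[res_a$genes$fdr <= fdr_cutoff, , drop = FALSE]
  if (nrow(sig_a) == 0)
    return(list(n_significant_a = 0L, n_replicated = 0L,
                replication_rate = NA_real_,
                direction_concordance = NA_real_))
  key_b <- paste(res_b$associations$variant_id, res_b$associations$gene_id)
  idx_b <- match(paste(sig_a$variant_id, sig_a$gene_id), key_b)
  if (all(is.na(idx_b))) stop("no overlap between the two pair spaces")
  sig_in_b <- res_b$genes$gene_id[res_b$genes$fdr <= fdr_cutoff]
  tested <- !is.na(idx_b)
  replicated <- tested & sig_a$gene_id %in% sig_in_b
  dir_match <- sign(sig_a$meta_z[replicated]) ==
    sign(res_b$associations$meta_z[idx_b[replicated]])
  list(
    n_significant_a = nrow(sig_a),
    n_replicated = sum(replicated),
    replication_rate = mean(replicated[tested]),
    direction_concordance = if (sum(replicated)) mean(dir_match) else NA_real_
  )
}

#' Genotype principal components for population structure
#'
#' PCA on the centered dosage matrix over a pruned, high-quality variant set
#' (same filters as duplicate detection) — the standard way samples are
#' grouped into ancestry clusters before stratified analysis.
#'
#' @param gt a [genotype_table()].
#' @param n_components number of PCs (default 4).
#' @param variants optional variant ids; defaults to
#'   [select_dedup_variants()] then [ld_prune()].
#' @return Matrix samples x components of PC scores.
#' @export
genotype_pca <- function(gt, n_components = 4, variants = NULL) {
  if (is.null(variants)) {
    variants <- tryCatch(
      ld_prune(gt, select_dedup_variants(gt)),
      error = function(e) gt$variants$variant_id)
  }
  d <- gt$dosage[match(variants, gt$variants$variant_id), , drop = FALSE]
  d <- d[apply(d, 1, stats::sd) > 0, , drop = FALSE]
  k <- min(n_components, ncol(d) - 1L, nrow(d))
  pc <- stats::prcomp(t(d), center = TRUE, scale. = FALSE)
  pc$x[, seq_len(k), drop = FALSE]
}
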