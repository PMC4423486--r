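#' Select high-quality variants for duplicate detection
#'
#' Keeps variants with estimated imputation dosage r-squared strictly above
#' `min_dr2`, MAF at least `min_maf` and call rate at least `min_call_rate`.
#'
#' @param gt a [genotype_table()].
#' @param min_dr2 strict lower bound on dosage r-squared (default 0.95).
#' @param min_maf inclusive MAF bound (default 0.05).
#' @param min_call_rate inclusive call-rate bound (default 0.95).
#' @return Character vector of retained variant ids.
#' @export
select_dedup_variants <- function(gt, min_dr2 = 0.95, min_maf = 0.05,
                                  min_call_rate = 0.95) {
  v <- gt$variants
  keep <- !is.na(v$dr2) & v$dr2 > min_dr2 &
    v$maf >= min_maf & v$call_rate >= min_call_rate
  if (!any(keep))
    stop("no variants pass the dedup filters; relax min_dr2/min_maf/min_call_rate")
  v$variant_id[keep]
}

# squared Pearson correlation between two dosage vectors over shared
# non-missing entries
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(0)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' LD-prune variants on dosage correlation
#'
#' Sliding-window pruning in the style of plink `--indep-pairwise`: within
#' each window of `window_variants` position-sorted variants, advanced by
#' `step` variants, pairs with dosage r-squared above `r2_threshold` are
#' broken by removing the variant with the lower MAF (tie: the later
#' position). On return no retained pair within any window exceeds the
#' threshold.
#'
#' @param gt a [genotype_table()], position-sorted within chromosome.
#' @param variants variant ids to consider (default: all).
#' @param window_variants window size in variant count (default 1000).
#' @param step window advance in variants (default 5).
#' @param r2_threshold prune when pairwise dosage r-squared exceeds this
#'   (default 0.2).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(gt, variants = NULL, window_variants = 1000, step = 5,
                     r2_threshold = 0.2) {
  v <- gt$variants
  idx <- if (is.null(variants)) seq_len(nrow(v)) else match(variants, v$variant_id)
  for (ch in unique(v$chrom[idx]))
    if (is.unsorted(v$pos[idx][v$chrom[idx] == ch]))
      stop("variants must be position-sorted within chromosome")
  keep <- rep(TRUE, length(idx))
  n <- length(idx)
  starts <- unique(c(seq(1L, max(1L, n - 1L), by = step)))
  for (s in starts) {
    w <- s:min(n, s + window_variants - 1L)
    w <- w[keep[w]]
    if (length(w) < 2) next
    d <- gt$dosage[idx[w], , drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))^2
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    while (TRUE) {
      mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[mx[1], mx[2]] <= r2_threshold) break
      pair <- sort(mx)
      maf <- gt$variants$maf[idx[w[pair]]]
      drop_local <- if (maf[1] < maf[2]) pair[1]
        else if (maf[2] < maf[1]) pair[2]
        else pair[which.max(gt$variants$pos[idx[w[pair]]])]
      keep[w[drop_local]] <- FALSE
      cc[drop_local, ] <- 0
      cc[, drop_local] <- 0
    }
  }
  v$variant_id[idx[keep]]
}

#' Pairwise genotype concordance between samples
#'
#' For every sample pair, the fraction of identical hard calls over the
#' sites non-missing in both. Pairs sharing fewer than `min_overlap` sites
#' are reported as `NA` (unknown) rather than risking a spurious merge.
#'
#' @param gt a [genotype_table()].
#' @param variants variant ids to compare on (default: all).
#' @param min_overlap minimum shared non-missing sites (default 100).
#' @return List of class `concordance_matrix` with symmetric matrices
#'   `concordance`, `n_compared`, `n_identical` (samples x samples,
#'   diagonal 1 / total).
#' @export
pairwise_concordance <- function(gt, variants = NULL, min_overlap = 100) {
  calls <- gt$calls
  if (!is.null(variants))
    calls <- calls[match(variants, gt$variants$variant_id), , drop = FALSE]
  nonmiss <- !is.na(calls)
  storage.mode(nonmiss) <- "double"
  n_compared <- crossprod(nonmiss)
  n_identical <- matrix(0, ncol(calls), ncol(calls),
                        dimnames = dimnames(n_compared))
  for (g in 0:2) {
    ind <- (!is.na(calls)) & calls == g
    storage.mode(ind) <- "double"
    n_identical <- n_identical + crossprod(ind)
  }
  conc <- n_identical / n_compared
  conc[n_compared < min_overlap] <- NA_real_
  diag(conc)[diag(n_compared) > 0] <- 1
  structure(list(concordance = conc, n_compared = n_compared,
                 n_identical = n_identical),
            class = "concordance_matrix")
}

#' Group duplicate samples and pick representatives
#'
#' Builds the graph with an edge between every pair whose concordance is at
#' or above `cutoff` and takes connected components as identity groups
#' (identity is treated as an equivalence relation). Within each group the
#' representative is chosen by ordered priority: reference-set membership,
#' then frequency of the sample's tissue in the cohort, then number of
#' expressed genes, with lexicographic sample id as the final tie-break.
#'
#' @param conc a `concordance_matrix` from [pairwise_concordance()].
#' @param sheet a [sample_sheet()].
#' @param cutoff concordance at or above which two samples are duplicates
#'   (default 0.78).
#' @return List of class `identity_groups`: `groups` (list of character
#'   vectors), `representatives` (one id per group), `keep` (all selected
#'   ids) and `drop` (ids to discard).
#' @export
group_and_select <- function(conc, sheet, cutoff = 0.78) {
  m <- conc$concordance
  ids <- colnames(m)
  adj <- !is.na(m) & m >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  tissue_freq <- table(sheet$tissue)
  groups <- split(ids, comp)
  names(groups) <- NULL
  reps <- vapply(groups, function(members) {
    i <- match(members, sheet$sample_id)
    ord <- order(-as.integer(sheet$is_reference_set[i]),
                 -as.numeric(tissue_freq[sheet$tissue[i]]),
                 -sheet$n_expressed_genes[i],
                 members)
    members[ord[1]]
  }, character(1))
  structure(list(groups = groups, representatives = reps,
                 keep = sort(reps), drop = sort(setdiff(ids, reps))),
            class = "identity_groups")
}

#' Per-variant dosage concordance against truth genotypes
#'
#' Squared Pearson correlation, across shared samples, between an imputed
#' dosage and a truth hard call at each shared variant, summarized by MAF
#' bin — the standard imputation-accuracy diagnostic.
#'
#' @param gt_rna [genotype_table()] with imputed dosages.
#' @param gt_truth [genotype_table()] with truth calls.
#' @param maf_bins breakpoints for MAF binning (on the truth table's MAF).
#' @return List with `per_variant` (variant_id, maf, r2) and `by_bin`
#'   (bin, n, median_r2, mean_r2); variants with zero truth variance are
#'   skipped and counted in `n_skipped`.
#' @export
dosage_concordance <- function(gt_rna, gt_truth,
                               maf_bins = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  shared_v <- intersect(gt_rna$variants$variant_id, gt_truth$variants$variant_id)
  shared_s <- intersect(gt_rna$samples, gt_truth$samples)
  if (!length(shared_v) || !length(shared_s))
    stop("no shared variants or samples between the two tables")
  d <- gt_rna$dosage[match(shared_v, gt_rna$variants$variant_id),
                     match(shared_s, gt_rna$samples), drop = FALSE]
  tr <- gt_truth$calls[match(shared_v, gt_truth$variants$variant_id),
                       match(shared_s, gt_truth$samples), drop = FALSE]
  maf <- gt_truth$variants$maf[match(shared_v, gt_truth$variants$variant_id)]
  r2 <- vapply(seq_along(shared_v), function(i) {
    y <- tr[i, ]
    ok <- !is.na(y) & !is.na(d[i, ])
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(d[i, ok], y[ok])^2
  }, numeric(1))
  skipped <- is.na(r2)
  pv <- data.frame(variant_id = shared_v, maf = maf, r2 = r2,
                   stringsAsFactors = FALSE)[!skipped, ]
  bin <- cut(pv$maf, maf_bins, include.lowest = TRUE)
  by_bin <- do.call(rbind, lapply(levels(bin), function(b) {
    x <- pv$r2[bin == b]
    data.frame(bin = b, n = length(x),
               median_r2 = if (length(x)) stats::median(x) else NA_real_,
               mean_r2 = if (length(x)) mean(x) else NA_real_)
  }))
  list(per_variant = pv, by_bin = by_bin, n_skipped = sum(skipped))
}
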