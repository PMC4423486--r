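#' Select sites eligible for allele-specific expression testing
#'
#' Applies the standard ASE site filters to an allelic count table: only
#' observations from samples called heterozygous with genotype quality
#' strictly above `min_gq` are kept; a site must then have at least
#' `min_het_samples` qualifying heterozygous samples, at least
#' `min_reads_per_allele` reads supporting each allele and at least
#' `min_allele_frac` of all reads supporting each allele (both inclusive),
#' mappability at or above `min_mappability`, and must not fall in an
#' excluded region (RNA-editing sites, splice-junction neighbourhoods,
#' repeats). The read-support filters apply to counts pooled across samples
#' by default — the test itself is pooled — or per sample with
#' `per_sample = TRUE` (then every qualifying sample must satisfy them).
#'
#' @param counts an allelic count table (see [read_allelic_counts()]).
#' @param gt a [genotype_table()] providing per-sample calls and GQ.
#' @param min_het_samples minimum qualifying het samples (default 5).
#' @param min_reads_per_allele minimum reads per allele (default 10).
#' @param min_allele_frac minimum fraction of all reads per allele
#'   (default 0.02).
#' @param min_gq strict lower bound on genotype quality (default 30).
#' @param min_mappability minimum mappability score (default 1).
#' @param per_sample logical; apply the read filters per sample instead of
#'   on pooled counts.
#' @return The filtered count table, containing only rows of eligible sites,
#'   with an `n_het_samples` attribute-free column joined per row.
#' @export
filter_ase_sites <- function(counts, gt, min_het_samples = 5,
                             min_reads_per_allele = 10,
                             min_allele_frac = 0.02, min_gq = 30,
                             min_mappability = 1, per_sample = FALSE) {
  df <- as.data.frame(counts)
  vi <- match(df$variant_id, gt$variants$variant_id)
  si <- match(df$sample_id, gt$samples)
  if (anyNA(vi) || anyNA(si))
    stop("allelic counts refer to variants or samples absent from the genotype table")
  is_het <- gt$calls[cbind(vi, si)] == 1L
  gq_ok <- gt$gq[cbind(vi, si)] > min_gq
  keep <- !is.na(is_het) & is_het & gq_ok &
    !df$in_excluded_region & df$mappability >= min_mappability
  df <- df[keep, , drop = FALSE]
  if (per_sample) {
    tot <- df$ref_count + df$alt_count
    ok <- df$ref_count >= min_reads_per_allele &
      df$alt_count >= min_reads_per_allele &
      df$ref_count >= min_allele_frac * tot &
      df$alt_count >= min_allele_frac * tot
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    warning("no observations survive the per-sample ASE filters")
    return(df)
  }
  agg <- rowsum(cbind(ref = df$ref_count, alt = df$alt_count,
                      n = rep(1L, nrow(df))), df$variant_id)
  tot <- agg[, "ref"] + agg[, "alt"]
  site_ok <- agg[, "n"] >= min_het_samples
  if (!per_sample) {
    site_ok <- site_ok &
      agg[, "ref"] >= min_reads_per_allele &
      agg[, "alt"] >= min_reads_per_allele &
      agg[, "ref"] >= min_allele_frac * tot &
      agg[, "alt"] >= min_allele_frac * tot
  }
  eligible <- rownames(agg)[site_ok]
  if (!length(eligible)) warning("no sites pass the ASE filters")
  out <- df[df$variant_id %in% eligible, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial likelihood-ratio test for allelic imbalance at one site
#'
#' Fits a single binomial success probability shared by all heterozygous
#' samples of the site by maximum likelihood — the closed form
#' `p_hat = pooled_alt / pooled_total` — and tests `p = 0.5` with the
#' likelihood ratio `2 * (l(p_hat) - l(0.5))`, where
#' `l(p) = sum_i [a_i log p + (t_i - a_i) log(1 - p)]` (binomial
#' coefficients cancel, and `0 * log 0` is 0). The p-value is the upper tail
#' of a chi-square with 1 df.
#'
#' @param ref_counts,alt_counts integer vectors over the het samples of one
#'   site.
#' @return List with `p_hat`, `lrt`, `p_value`, `pooled_ref`, `pooled_alt`.
#' @export
binomial_lrt <- function(ref_counts, alt_counts) {
  a <- sum(alt_counts)
  r <- sum(ref_counts)
  tot <- a + r
  if (tot == 0) stop("no reads at site")
  p_hat <- a / tot
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll_hat <- xlogy(a, p_hat) + xlogy(r, 1 - p_hat)
  ll_null <- tot * log(0.5)
  lrt <- max(0, 2 * (ll_hat - ll_null))
  list(p_hat = p_hat, lrt = lrt,
       p_value = max(stats::pchisq(lrt, df = 1, lower.tail = FALSE), 1e-300),
       pooled_ref = r, pooled_alt = a)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector in (0, 1\].
#' @return Adjusted values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Test every eligible site for allele-specific expression
#'
#' Runs [filter_ase_sites()], then the per-site binomial likelihood-ratio
#' test, and controls the FDR across sites with Benjamini-Hochberg. The
#' direction is `alt_higher`/`ref_higher` by the sign of `p_hat - 0.5`
#' (`balanced` at exactly 0.5). The mean `p_hat` across tested sites is
#' returned as a reference-bias diagnostic: under unbiased sampling it
#' should sit near 0.5.
#'
#' @param counts allelic count table.
#' @param gt a [genotype_table()].
#' @param ... filter settings passed to [filter_ase_sites()].
#' @return List with `sites` (data.frame: `variant_id`, `n_het_samples`,
#'   `pooled_ref`, `pooled_alt`, `p_hat`, `lrt`, `p_value`, `fdr`,
#'   `direction`) and `ref_bias_diagnostic` (mean p_hat).
#' @export
ase_test <- function(counts, gt, ...) {
  df <- filter_ase_sites(counts, gt, ...)
  if (nrow(df) == 0)
    return(list(sites = data.frame(), ref_bias_diagnostic = NA_real_))
  # pooled counts per site; the shared-p likelihood depends on the site only
  # through these sums, so this is exactly binomial_lrt() per site
  pooled <- rowsum(cbind(ref = df$ref_count, alt = df$alt_count,
                         n = rep(1L, nrow(df))), df$variant_id)
  a <- pooled[, "alt"]; r <- pooled[, "ref"]; tot <- a + r
  p_hat <- a / tot
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  lrt <- pmax(0, 2 * (xlogy(a, p_hat) + xlogy(r, 1 - p_hat) - tot * log(0.5)))
  sites <- data.frame(variant_id = rownames(pooled),
                      n_het_samples = as.integer(pooled[, "n"]),
                      pooled_ref = as.integer(r), pooled_alt = as.integer(a),
                      p_hat = p_hat, lrt = lrt,
                      p_value = pmax(stats::pchisq(lrt, df = 1,
                                                   lower.tail = FALSE), 1e-300),
                      stringsAsFactors = FALSE, row.names = NULL)
  sites$fdr <- bh_fdr(sites$p_value)
  sites$direction <- ifelse(sites$p_hat > 0.5, "alt_higher",
                            ifelse(sites$p_hat < 0.5, "ref_higher", "balanced"))
  list(sites = sites, ref_bias_diagnostic = mean(sites$p_hat))
}

#' Allelic-direction concordance between ASE and eQTL results
#'
#' Among (variant, gene) pairs where the variant shows significant allelic
#' imbalance and a significant eQTL effect on the gene — the gene passes the
#' gene-level FDR cutoff and the SNP itself is nominally associated
#' (`p < pair_p`) with it — the fraction where the ASE direction matches the
#' eQTL direction (positive meta-z meaning the alt allele increases
#' expression).
#'
#' @param ase_sites `sites` data.frame from [ase_test()].
#' @param eqtl_res result of [permutation_fdr()].
#' @param variant_gene data.frame mapping `variant_id` to `gene_id` (e.g.
#'   the cis pairs); only mapped variants can be compared.
#' @param fdr_cutoff significance cutoff for both analyses (default 0.05).
#' @param pair_p nominal association p required of the SNP-gene pair itself,
#'   so that a significant gene's unassociated cis SNPs do not enter
#'   (default 0.05).
#' @return List with `n_shared`, `concordance` (fraction matching).
#' @export
direction_concordance <- function(ase_sites, eqtl_res, variant_gene,
                                  fdr_cutoff = 0.05, pair_p = 0.05) {
  sig_ase <- ase_sites[ase_sites$fdr <= fdr_cutoff &
                         ase_sites$direction != "balanced", , drop = FALSE]
  sig_genes <- eqtl_res$genes$gene_id[eqtl_res$genes$fdr <= fdr_cutoff]
  assoc <- eqtl_res$associations
  assoc <- assoc[assoc$gene_id %in% sig_genes &
                   !is.na(assoc$p_value) & assoc$p_value < pair_p, , drop = FALSE]
  key <- paste(variant_gene$variant_id, variant_gene$gene_id)
  assoc <- assoc[paste(assoc$variant_id, assoc$gene_id) %in% key, , drop = FALSE]
  shared <- merge(sig_ase[, c("variant_id", "direction")],
                  assoc[, c("variant_id", "gene_id", "meta_z")],
                  by = "variant_id")
  if (nrow(shared) == 0)
    stop("no (variant, gene) pairs significant in both analyses")
  eqtl_dir <- ifelse(shared$meta_z > 0, "alt_higher", "ref_higher")
  list(n_shared = nrow(shared),
       concordance = mean(shared$direction == eqtl_dir))
}

#' Summarize allelic imbalance by functional class
#'
#' Per externally supplied variant category (e.g. nonsense / missense /
#' synonymous), summarizes the distribution of alt-allele fractions and
#' compares each category against all remaining sites with a Wilcoxon
#' rank-sum test. Categories with fewer than 2 sites are reported without a
#' test.
#'
#' @param ase_sites `sites` data.frame from [ase_test()].
#' @param class_labels data.frame `variant_id`, `category`.
#' @return data.frame per category: `n`, `mean_p_hat`, `median_p_hat`,
#'   `rank_sum_p` (NA when untestable).
#' @export
class_direction_summary <- function(ase_sites, class_labels) {
  df <- merge(ase_sites[, setdiff(names(ase_sites), "category")],
              class_labels, by = "variant_id")
  if (nrow(df) == 0) stop("no labelled sites")
  cats <- sort(unique(df$category))
  out <- lapply(cats, function(cc) {
    x <- df$p_hat[df$category == cc]
    y <- df$p_hat[df$category != cc]
    p <- if (length(x) >= 2 && length(y) >= 2)
      stats::wilcox.test(x, y)$p.value else NA_real_
    data.frame(category = cc, n = length(x), mean_p_hat = mean(x),
               median_p_hat = stats::median(x), rank_sum_p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
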