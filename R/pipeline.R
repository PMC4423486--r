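#' Pipeline configuration with standard defaults
#'
#' All stage thresholds in one validated list: heterozygosity bounds 0.2/0.4
#' (exclusive), duplicate concordance cutoff 0.78, dedup variant filters
#' (dosage r-squared > 0.95, MAF >= 0.05, call rate >= 0.95), pruning window
#' 1000 variants / step 5 / r-squared 0.2, cis window 250 kb, eQTL variant
#' dosage r-squared >= 0.8, ASE filters (5 het samples, 10 reads per allele,
#' 2% per allele, GQ > 30, mappability 1), FDR 0.05.
#'
#' @param ... overrides for any default; unknown keys are rejected.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    het_low = 0.2, het_high = 0.4,
    het_min_maf = 0.05, het_min_depth = 10, het_min_sites = 50,
    pc_outlier_component = 1, pc_outlier_cutoff = 4,
    dup_cutoff = 0.78,
    dedup_min_dr2 = 0.95, dedup_min_maf = 0.05, dedup_min_call_rate = 0.95,
    prune_window = 1000, prune_step = 5, prune_r2 = 0.2,
    cis_window = 250000, eqtl_min_dr2 = 0.8, eqtl_min_maf = 0.05,
    eqtl_min_n = 30, n_genotype_pcs = 4, n_expr_pcs = NULL,
    ase_min_het_samples = 5, ase_min_reads_per_allele = 10,
    ase_min_allele_frac = 0.02, ase_min_gq = 30, ase_min_mappability = 1,
    fdr = 0.05, n_perm = 10, seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$het_low >= cfg$het_high)
    stop("het_low must be below het_high")
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on an input bundle
#'
#' Loads the bundle (`genotypes.vcf`, `expression.tsv`,
#' `allelic_counts.tsv`, `sample_sheet.tsv`, optional `exclusions.bed` /
#' `mappability.bed`), then chains sample QC, duplicate removal,
#' normalization, cis-eQTL mapping with permutation FDR and ASE testing,
#' writing each stage's result tables plus the serialized configuration to
#' `output_dir`. Reruns with the same config and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param input_dir directory with the input bundle (e.g. from
#'   [simulate_bundle()]).
#' @param output_dir directory for result TSVs (created if absent).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), input_dir, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (check its inputs in ", input_dir, ")", call. = FALSE))
  }
  gt <- stage("load", read_genotypes(file.path(input_dir, "genotypes.vcf")))
  expr <- stage("load", read_expression(file.path(input_dir, "expression.tsv")))
  sheet <- stage("load", read_sample_sheet(file.path(input_dir, "sample_sheet.tsv")))
  excl <- Filter(file.exists, file.path(input_dir, "exclusions.bed"))
  mapp <- file.path(input_dir, "mappability.bed")
  counts <- stage("load", read_allelic_counts(
    file.path(input_dir, "allelic_counts.tsv"), exclusions = excl,
    mappability = if (file.exists(mapp)) mapp else NULL))

  # sample QC on quantile-normalized log2 expression
  qc <- stage("qc", {
    qn <- quantile_normalize(expr)
    qn$values <- log2(qn$values + 1)
    run_sample_qc(qn, gt, sheet,
                  pc_component = config$pc_outlier_component,
                  pc_cutoff = config$pc_outlier_cutoff,
                  het_low = config$het_low, het_high = config$het_high,
                  min_maf = config$het_min_maf,
                  min_depth = config$het_min_depth,
                  min_sites = config$het_min_sites)
  })
  write_results(qc, file.path(output_dir, "qc_report.tsv"))
  pass <- qc$sample_id[qc$flags == ""]

  gt_pass <- subset_genotypes(gt, samples = pass)
  sheet_pass <- sheet[sheet$sample_id %in% pass, , drop = FALSE]

  dedup <- stage("dedupe", {
    vars <- ld_prune(gt_pass, select_dedup_variants(
      gt_pass, min_dr2 = config$dedup_min_dr2,
      min_maf = config$dedup_min_maf,
      min_call_rate = config$dedup_min_call_rate),
      window_variants = config$prune_window, step = config$prune_step,
      r2_threshold = config$prune_r2)
    conc <- pairwise_concordance(gt_pass, vars)
    group_and_select(conc, sheet_pass, cutoff = config$dup_cutoff)
  })
  utils::write.table(data.frame(sample_id = dedup$keep),
                     file.path(output_dir, "kept_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- dedup$keep
  gt_u <- subset_genotypes(gt_pass, samples = keep)
  sheet_u <- sheet_pass[sheet_pass$sample_id %in% keep, , drop = FALSE]
  expr_u <- expr
  expr_u$values <- expr$values[, keep, drop = FALSE]
  expr_u$total_mapped_reads <- expr$total_mapped_reads[match(keep, colnames(expr$values))]

  norm <- stage("normalize", {
    gpc <- genotype_pca(gt_u, n_components = config$n_genotype_pcs)
    normalize_for_eqtl(expr_u, genotype_pcs = gpc,
                       n_expr_pcs = config$n_expr_pcs)
  })

  eqtl <- stage("eqtl", {
    pairs <- build_cis_pairs(gt_u, expr_u, window_bp = config$cis_window,
                             min_dr2 = config$eqtl_min_dr2,
                             min_maf = config$eqtl_min_maf)
    permutation_fdr(pairs, gt_u, norm$residuals, sheet_u,
                    n_perm = config$n_perm, seed = config$seed,
                    min_n = config$eqtl_min_n)
  })
  write_results(eqtl$genes, file.path(output_dir, "eqtl_genes.tsv"))
  write_results(eqtl$associations, file.path(output_dir, "eqtl_associations.tsv"))

  ase <- stage("ase", ase_test(
    counts[counts$sample_id %in% keep, , drop = FALSE], gt_u,
    min_het_samples = config$ase_min_het_samples,
    min_reads_per_allele = config$ase_min_reads_per_allele,
    min_allele_frac = config$ase_min_allele_frac,
    min_gq = config$ase_min_gq,
    min_mappability = config$ase_min_mappability))
  if (nrow(ase$sites)) write_results(ase$sites, file.path(output_dir, "ase_sites.tsv"))

  jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(qc = qc, dedup = dedup, normalization = norm,
                 eqtl = eqtl, ase = ase, kept_samples = keep))
}
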