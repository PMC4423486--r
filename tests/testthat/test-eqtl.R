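toy_cis <- function() {
  # 3 genes (centers 10k, 300k, 600k), 5 variants with chosen attributes
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 5), 5, 4, byrow = TRUE,
                  dimnames = list(NULL, paste0("s", 1:4)))
  gt <- make_gt(calls, dr2 = c(0.9, 0.79, 0.9, 0.9, 0.9),
                pos = c(10000L, 20000L, 260000L, 300000L, 600000L))
  gt$variants$maf <- 0.25
  expr <- make_expr(matrix(1.0, 3, 4, dimnames = list(NULL, paste0("s", 1:4))),
                    centers = c(10000L, 300000L, 600000L))
  list(gt = gt, expr = expr)
}

test_that("cis pairs respect the window and variant filters", {
  fx <- toy_cis()
  pairs <- build_cis_pairs(fx$gt, fx$expr)
  # hand enumeration: gene1 (center 10k) pairs v1 (0 bp) and v3 (exactly
  # 250 kb, inclusive), never v2 (dr2 0.79 < 0.8); gene2 (300k) pairs v3
  # (40 kb) and v4 (0 bp) but not v1 (290 kb); gene3 (600k) pairs v5 only
  expected <- rbind(
    c("v001", "g001"), c("v003", "g001"),
    c("v003", "g002"), c("v004", "g002"),
    c("v005", "g003"))
  got <- pairs[order(pairs$gene_id, pairs$variant_id), c("variant_id", "gene_id")]
  expect_equal(unname(as.matrix(got)), unname(expected[order(expected[, 2], expected[, 1]), ]))
  # exact 250 kb boundary is inclusive
  expect_true(any(pairs$distance == 250000))
})

test_that("rank association matches a brute-force Spearman oracle", {
  set.seed(80)
  calls <- matrix(rbinom(6 * 4, 2, 0.5), 4, 6,
                  dimnames = list(NULL, paste0("s", 1:6)))
  dosage <- calls + matrix(runif(24, -0.1, 0.1), 4, 6)
  dosage <- pmin(pmax(dosage, 0), 2); dimnames(dosage) <- dimnames(calls)
  gt <- make_gt(calls, dosage = dosage, dr2 = 0.9)
  v <- matrix(rnorm(3 * 6), 3, 6, dimnames = list(NULL, paste0("s", 1:6)))
  expr <- make_expr(v)
  pairs <- expand.grid(variant_id = gt$variants$variant_id,
                       gene_id = expr$genes$gene_id,
                       stringsAsFactors = FALSE)
  pairs$distance <- 0
  res <- associate_population(pairs, gt, expr, paste0("s", 1:6))
  for (i in seq_len(nrow(res))) {
    x <- dosage[match(res$variant_id[i], gt$variants$variant_id), ]
    y <- v[match(res$gene_id[i], expr$genes$gene_id), ]
    rho_oracle <- cor(rank(x), rank(y))    # Spearman as Pearson on ranks
    expect_equal(res$rho[i], rho_oracle, tolerance = 1e-12)
  }
  # strictly increasing function of dosage gives rho = 1
  vmono <- matrix(2^dosage[1, ], 1, 6, dimnames = list(NULL, paste0("s", 1:6)))
  resm <- associate_population(
    data.frame(variant_id = "v001", gene_id = "g001", distance = 0),
    gt, make_expr(vmono), paste0("s", 1:6))
  expect_equal(resm$rho, 1)
})

test_that("null association z-scores are standard-normal calibrated", {
  set.seed(81)
  n <- 100; nv <- 500
  calls <- matrix(rbinom(nv * n, 2, runif(nv, 0.2, 0.8)), nv, n,
                  dimnames = list(NULL, sprintf("s%03d", 1:n)))
  gt <- make_gt(calls, dr2 = 0.99)
  v <- matrix(rnorm(nv * n), nv, n, dimnames = list(NULL, colnames(calls)))
  expr <- make_expr(v)
  pairs <- data.frame(variant_id = gt$variants$variant_id,
                      gene_id = expr$genes$gene_id, distance = 0)
  res <- associate_population(pairs, gt, expr, colnames(calls))
  z <- res$z[!is.na(res$z)]
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("meta-analysis obeys its algebraic identities", {
  # single population: meta_z equals z exactly
  m1 <- meta_analyze(z = matrix(2.345), n = matrix(57))
  expect_equal(m1$meta_z, 2.345)
  # equal n, opposite z: exact cancellation
  m2 <- meta_analyze(z = matrix(c(1.7, -1.7), 1), n = matrix(c(80, 80), 1))
  expect_equal(m2$meta_z, 0)
  # plug-in check
  m3 <- meta_analyze(z = matrix(c(2, 1), 1), n = matrix(c(100, 50), 1))
  expect_equal(m3$meta_z, (2 * sqrt(100) + 1 * sqrt(50)) / sqrt(150))
  # population order is irrelevant
  m4 <- meta_analyze(z = matrix(c(1, 2), 1), n = matrix(c(50, 100), 1))
  expect_equal(abs(m4$meta_z), abs(m3$meta_z))
  # a population with NA z drops out of the weights
  m5 <- meta_analyze(z = matrix(c(2, NA), 1), n = matrix(c(100, 50), 1))
  expect_equal(m5$meta_z, 2)
})

test_that("within-study permutation preserves each study's sample multiset", {
  cfg <- sim_config(n_samples = c(EUR = 40), n_studies = 3, n_genes = 30,
                    n_variants = 20, sex_genes = FALSE, seed = 82)
  sim <- simulate_expression(cfg, simulate_genotypes(cfg))
  resid <- log_center_scale(sim$expression, factors = 1)
  set.seed(1)
  perm <- rnaqtl:::permute_within_study(resid, sim$sheet)
  expect_identical(colnames(perm$values), colnames(resid$values))
  # each sample's permuted expression comes from a sample of the same study
  for (st in unique(sim$sheet$study_id)) {
    members <- sim$sheet$sample_id[sim$sheet$study_id == st]
    sub_orig <- resid$values[, members]
    sub_perm <- perm$values[, members]
    expect_equal(sort(unname(colSums(sub_orig))),
                 sort(unname(colSums(sub_perm))), tolerance = 1e-12)
  }
})

test_that("no-op permutations force FDR to one everywhere", {
  # every study has a single sample, so the permuted data equal the real data
  set.seed(83)
  n <- 12
  calls <- matrix(rbinom(20 * n, 2, 0.5), 20, n,
                  dimnames = list(NULL, sprintf("s%02d", 1:n)))
  gt <- make_gt(calls, dr2 = 0.9)
  v <- matrix(rnorm(5 * n), 5, n, dimnames = list(NULL, colnames(calls)))
  expr <- make_expr(v, centers = rep(5000L, 5))
  sheet <- sample_sheet(data.frame(
    sample_id = colnames(calls), study_id = colnames(calls),
    population = "EUR", tissue = "t"))
  pairs <- build_cis_pairs(gt, expr, min_maf = 0)
  expect_warning(
    res <- permutation_fdr(pairs, gt, expr, sheet, n_perm = 3, min_n = 3),
    "single sample")
  expect_true(all(res$genes$fdr == 1))
})

test_that("planted cis effects are detected with controlled error", {
  cfg <- sim_config(n_samples = c(EUR = 60, AFR = 60), n_studies = 2,
                    n_genes = 100, n_variants = 150, eqtl_frac = 0.1,
                    eqtl_beta = 1.5, sex_genes = FALSE, seed = 84)
  sim <- simulate_expression(cfg, simulate_genotypes(cfg))
  norm <- normalize_for_eqtl(sim$expression, n_expr_pcs = 5)
  pairs <- build_cis_pairs(sim$genotypes, sim$expression)
  res <- permutation_fdr(pairs, sim$genotypes, norm$residuals, sim$sheet,
                         n_perm = 5, seed = 85)
  sig <- res$genes$gene_id[res$genes$fdr <= 0.05]
  planted <- sim$truth$eqtl$gene_id
  expect_gt(mean(planted %in% sig), 0.5)
  expect_lt(mean(!(sig %in% planted)), 0.1)
})

test_that("replication is exact on itself and sign-sensitive", {
  cfg <- sim_config(n_samples = c(EUR = 50), n_genes = 40, n_variants = 60,
                    eqtl_frac = 0.2, eqtl_beta = 2, sex_genes = FALSE,
                    seed = 86)
  sim <- simulate_expression(cfg, simulate_genotypes(cfg))
  norm <- normalize_for_eqtl(sim$expression, n_expr_pcs = 3)
  pairs <- build_cis_pairs(sim$genotypes, sim$expression)
  res <- permutation_fdr(pairs, sim$genotypes, norm$residuals, sim$sheet,
                         n_perm = 5, seed = 87)
  self <- replicate_eqtl(res, res)
  expect_gt(self$n_significant_a, 0)
  expect_equal(self$replication_rate, 1)
  expect_equal(self$direction_concordance, 1)
  flipped <- res
  flipped$associations$meta_z <- -flipped$associations$meta_z
  opp <- replicate_eqtl(res, flipped)
  expect_equal(opp$direction_concordance, 0)
})
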