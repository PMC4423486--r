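# allelic count table + genotype table where every listed sample is het
make_ase_fixture <- function(ref, alt, n_samples = length(ref),
                             gq = 99, mapp = 1, excluded = FALSE) {
  samples <- sprintf("s%02d", seq_len(n_samples))
  calls <- matrix(1L, 1, n_samples, dimnames = list(NULL, samples))
  gqm <- matrix(gq, 1, n_samples, dimnames = dimnames(calls))
  gt <- make_gt(calls, gq = gqm)
  counts <- data.frame(variant_id = "v001", chrom = "1", pos = 1000L,
                       sample_id = samples[seq_along(ref)],
                       ref_count = ref, alt_count = alt,
                       in_excluded_region = excluded, mappability = mapp,
                       stringsAsFactors = FALSE)
  list(counts = counts, gt = gt)
}

test_that("site filters enforce the het-sample, read and quality thresholds", {
  # 4 het samples: below the minimum of 5
  fx <- make_ase_fixture(rep(10L, 4), rep(10L, 4))
  expect_warning(out <- filter_ase_sites(fx$counts, fx$gt), "no sites")
  expect_equal(nrow(out), 0)
  # 9 alt reads pooled: below 10 per allele
  fx2 <- make_ase_fixture(rep(200L, 5), c(2L, 2L, 2L, 2L, 1L))
  expect_warning(out2 <- filter_ase_sites(fx2$counts, fx2$gt), "no sites")
  expect_equal(nrow(out2), 0)
  # exactly 2% of pooled reads on the alt allele: inclusive boundary
  fx3 <- make_ase_fixture(rep(196L, 5), rep(4L, 5))  # 20/1000
  out3 <- filter_ase_sites(fx3$counts, fx3$gt)
  expect_equal(nrow(out3), 5)
  # GQ exactly 30 fails the strict "above 30" rule
  fx4 <- make_ase_fixture(rep(20L, 6), rep(20L, 6), gq = 30)
  expect_warning(out4 <- filter_ase_sites(fx4$counts, fx4$gt), "no")
  expect_equal(nrow(out4), 0)
  # excluded regions and sub-unit mappability drop the site
  fx5 <- make_ase_fixture(rep(20L, 6), rep(20L, 6), excluded = TRUE)
  expect_warning(expect_equal(nrow(filter_ase_sites(fx5$counts, fx5$gt)), 0))
  fx6 <- make_ase_fixture(rep(20L, 6), rep(20L, 6), mapp = 0.9)
  expect_warning(expect_equal(nrow(filter_ase_sites(fx6$counts, fx6$gt)), 0))
  # per-sample semantics drops individual low-coverage observations
  fx7 <- make_ase_fixture(c(rep(20L, 6), 3L), c(rep(20L, 6), 3L))
  out7 <- filter_ase_sites(fx7$counts, fx7$gt, per_sample = TRUE)
  expect_equal(nrow(out7), 6)
})

test_that("non-heterozygous observations are excluded from testing", {
  fx <- make_ase_fixture(rep(20L, 6), rep(20L, 6))
  fx$gt$calls[1, 1] <- 0L
  out <- filter_ase_sites(fx$counts, fx$gt)
  expect_equal(nrow(out), 5)
  expect_false("s01" %in% out$sample_id)
})

test_that("the binomial LRT has its closed-form properties", {
  # balanced counts: p_hat one half, zero statistic, p-value 1
  fit <- binomial_lrt(50L, 50L)
  expect_equal(fit$p_hat, 0.5)
  expect_equal(fit$lrt, 0)
  expect_equal(fit$p_value, 1)
  # single-sample 30/100: evaluates the known closed form
  fit2 <- binomial_lrt(70L, 30L)
  expect_equal(fit2$lrt,
               2 * (30 * log(0.3) + 70 * log(0.7) - 100 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(fit2$lrt, 16.456576, tolerance = 1e-5)
  # pooling equivalence: identical pooled counts, identical statistic
  multi <- binomial_lrt(c(7L, 6L), c(3L, 4L))
  single <- binomial_lrt(13L, 7L)
  expect_identical(multi$lrt, single$lrt)
  # degenerate all-alt counts stay finite (0*log0 = 0)
  expect_true(is.finite(binomial_lrt(0L, 25L)$lrt))
  expect_error(binomial_lrt(0L, 0L), "no reads")
})

test_that("the LRT matches an independent likelihood oracle", {
  set.seed(90)
  for (i in 1:200) {
    k <- sample(1:8, 1)
    tot <- sample(5:200, k, replace = TRUE)
    alt <- rbinom(k, tot, runif(1, 0.05, 0.95))
    fit <- binomial_lrt(tot - alt, alt)
    expect_equal(fit$lrt, lrt_oracle(tot - alt, alt), tolerance = 1e-9)
    expect_gte(fit$lrt, 0)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(91)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("ase_test aggregates per site and controls FDR", {
  samples <- sprintf("s%02d", 1:10)
  calls <- matrix(1L, 3, 10, dimnames = list(NULL, samples))
  gt <- make_gt(calls, gq = matrix(99, 3, 10, dimnames = dimnames(calls)))
  counts <- do.call(rbind, lapply(1:3, function(v) {
    data.frame(variant_id = sprintf("v%03d", v), chrom = "1",
               pos = v * 1000L, sample_id = samples,
               ref_count = if (v == 1) 80L else 50L, alt_count = 50L,
               in_excluded_region = FALSE, mappability = 1,
               stringsAsFactors = FALSE)
  }))
  res <- ase_test(counts, gt)
  expect_equal(nrow(res$sites), 3)
  expect_equal(res$sites$n_het_samples, rep(10L, 3))
  v1 <- res$sites[res$sites$variant_id == "v001", ]
  expect_equal(v1$p_hat, 500 / 1300)
  expect_equal(v1$lrt, lrt_oracle(rep(80L, 10), rep(50L, 10)),
               tolerance = 1e-9)
  expect_equal(v1$direction, "ref_higher")
  expect_equal(res$sites$fdr, bh_oracle(res$sites$p_value), tolerance = 1e-12)
})

test_that("ASE/eQTL direction concordance counts matching signs", {
  ase_sites <- data.frame(variant_id = c("v1", "v2"), p_hat = c(0.8, 0.2),
                          fdr = c(0.01, 0.01),
                          direction = c("alt_higher", "ref_higher"))
  eqtl_res <- list(
    genes = data.frame(gene_id = c("g1", "g2"), fdr = c(0.01, 0.01)),
    associations = data.frame(variant_id = c("v1", "v2"),
                              gene_id = c("g1", "g2"),
                              meta_z = c(3, 4), p_value = c(0.001, 0.001)))
  vg <- data.frame(variant_id = c("v1", "v2"), gene_id = c("g1", "g2"))
  out <- direction_concordance(ase_sites, eqtl_res, vg)
  expect_equal(out$n_shared, 2)
  expect_equal(out$concordance, 0.5)   # v1 matches, v2 does not
  # single matching pair gives 1
  out1 <- direction_concordance(ase_sites[1, ], eqtl_res, vg[1, ])
  expect_equal(out1$concordance, 1)
  # empty intersection errors
  expect_error(direction_concordance(ase_sites[ase_sites$fdr > 1, ],
                                     eqtl_res, vg), "no .variant")
})

test_that("class summaries detect a planted directional category", {
  set.seed(92)
  n <- 100
  mk <- function(p, pre) data.frame(
    variant_id = sprintf("%s%03d", pre, 1:n),
    p_hat = rbinom(n, 200, p) / 200, stringsAsFactors = FALSE)
  sites <- rbind(cbind(mk(0.3, "a"), category = "nonsense"),
                 cbind(mk(0.5, "b"), category = "background"))
  out <- class_direction_summary(sites, sites[, c("variant_id", "category")])
  expect_lt(out$rank_sum_p[out$category == "nonsense"], 0.01)
  expect_lt(out$mean_p_hat[out$category == "nonsense"], 0.4)
  # a single-category table is reported without a test
  one <- class_direction_summary(sites[sites$category == "nonsense", ],
                                 sites[, c("variant_id", "category")])
  expect_true(is.na(one$rank_sum_p))
})
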