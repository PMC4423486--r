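test_that("dedup variant filters apply the stated boundary semantics", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 5), 5, 4, byrow = TRUE,
                  dimnames = list(NULL, paste0("s", 1:4)))
  gt <- make_gt(calls, dr2 = c(0.95, 0.99, 0.96, 0.99, 0.99))
  gt$variants$maf <- c(0.3, 0.05, 0.04, 0.3, 0.3)
  gt$variants$call_rate <- c(1, 1, 1, 0.9, 1)
  # v1: dr2 exactly 0.95 is excluded (strict); v3 fails maf; v4 fails call rate
  expect_setequal(select_dedup_variants(gt), c("v002", "v005"))
  gt$variants$dr2 <- 0.5
  expect_error(select_dedup_variants(gt), "relax")
})

test_that("LD pruning removes correlated variants and keeps independent ones", {
  set.seed(50)
  base <- rbinom(40, 2, 0.5)
  dosage <- rbind(base, base, rbinom(40, 2, 0.5))
  calls <- matrix(as.integer(round(dosage)), 3, 40,
                  dimnames = list(NULL, paste0("s", 1:40)))
  dimnames(dosage) <- dimnames(calls)
  gt <- make_gt(calls, dosage = dosage)
  kept <- ld_prune(gt)
  expect_length(kept, 2)           # one of the perfect pair dropped
  # independent variants all retained
  set.seed(51)
  d2 <- matrix(rbinom(200, 2, 0.5) + 0.0, 5, 40,
               dimnames = list(NULL, paste0("s", 1:40)))
  gt2 <- make_gt(matrix(as.integer(d2), 5, 40, dimnames = dimnames(d2)),
                 dosage = d2)
  cc <- cor(t(d2))^2
  if (max(cc[upper.tri(cc)]) < 0.2)
    expect_length(ld_prune(gt2), 5)
})

test_that("pruned sets pass an exhaustive within-window r2 scan", {
  set.seed(52)
  for (rep in 1:5) {
    # copied-with-noise blocks create realistic LD
    n <- 40
    blocks <- lapply(1:4, function(i) {
      seed_v <- rbinom(n, 2, runif(1, 0.2, 0.8))
      t(sapply(1:5, function(j)
        pmin(2, pmax(0, seed_v + rnorm(n, 0, runif(1, 0.1, 1))))))
    })
    dosage <- do.call(rbind, blocks)
    colnames(dosage) <- paste0("s", 1:n)
    calls <- matrix(as.integer(round(dosage)), nrow(dosage), n,
                    dimnames = dimnames(dosage))
    gt <- make_gt(calls, dosage = dosage)
    kept <- ld_prune(gt, window_variants = 20, step = 5, r2_threshold = 0.2)
    d <- gt$dosage[match(kept, gt$variants$variant_id), , drop = FALSE]
    if (length(kept) > 1) {
      cc <- cor(t(d))^2
      expect_lte(max(cc[upper.tri(cc)]), 0.2 + 1e-12)
    }
  }
  # unsorted input is rejected
  gtu <- make_gt(matrix(0:2, 3, 4, dimnames = list(NULL, paste0("s", 1:4))),
                 pos = c(3000L, 1000L, 2000L))
  expect_error(ld_prune(gtu), "sorted")
})

test_that("pairwise concordance counts identical calls over shared sites", {
  calls <- cbind(a = c(1L, 1L, 0L), b = c(1L, 2L, 0L))
  gt <- make_gt(calls)
  conc <- pairwise_concordance(gt, min_overlap = 1)
  expect_equal(conc$concordance["a", "b"], 2 / 3)
  expect_equal(conc$concordance["a", "a"], 1)
  expect_equal(conc$concordance, t(conc$concordance))
  expect_equal(conc$n_compared["a", "b"], 3)
  # sparse pairs are unknown, never merged
  calls2 <- cbind(a = c(1L, NA), b = c(1L, 1L))
  conc2 <- pairwise_concordance(make_gt(calls2), min_overlap = 2)
  expect_true(is.na(conc2$concordance["a", "b"]))
})

test_that("identity groups are connected components with priority selection", {
  ids <- c("A", "B", "C", "D")
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(m) <- 1
  m["A", "B"] <- m["B", "A"] <- 0.9
  m["B", "C"] <- m["C", "B"] <- 0.85
  conc <- structure(list(concordance = m,
                         n_compared = matrix(1000, 4, 4, dimnames = list(ids, ids))),
                    class = "concordance_matrix")
  sheet <- sample_sheet(data.frame(
    sample_id = ids, study_id = "s1", population = "EUR",
    tissue = c("blood", "blood", "brain", "blood"),
    is_reference_set = c(FALSE, FALSE, TRUE, FALSE),
    n_expressed_genes = c(100L, 500L, 50L, 10L)))
  gr <- group_and_select(conc, sheet, cutoff = 0.78)
  # A-B and B-C connect A, B, C transitively; D alone
  expect_length(gr$groups, 2)
  expect_setequal(gr$groups[[which(lengths(gr$groups) == 3)]], c("A", "B", "C"))
  # C wins on the reference-set flag despite rarer tissue / fewer genes
  expect_true("C" %in% gr$representatives)
  expect_setequal(gr$drop, c("A", "B"))
  # without the flag, tissue frequency then expressed genes decide
  sheet$is_reference_set <- FALSE
  gr2 <- group_and_select(conc, sheet, cutoff = 0.78)
  expect_true("B" %in% gr2$representatives)  # blood (3x) over brain, 500 genes
  # no pair above cutoff: every sample its own group
  gr3 <- group_and_select(conc, sheet, cutoff = 0.99)
  expect_length(gr3$groups, 4)
  expect_length(gr3$drop, 0)
})

test_that("planted duplicates are recovered with no false merges", {
  for (seed in c(101, 102, 103)) {
    cfg <- sim_config(n_samples = c(EUR = 25, AFR = 25), n_genes = 10,
                      n_variants = 2500, dup_pairs = 2, sex_genes = FALSE,
                      seed = seed)
    sim <- simulate_genotypes(cfg)
    vars <- ld_prune(sim$genotypes, select_dedup_variants(sim$genotypes))
    conc <- pairwise_concordance(sim$genotypes, vars)
    gr <- group_and_select(conc, sim$sheet, cutoff = 0.78)
    dup_groups <- gr$groups[lengths(gr$groups) > 1]
    expect_length(dup_groups, 2)
    for (pair_row in seq_len(nrow(sim$truth$duplicate_pairs))) {
      pair <- sim$truth$duplicate_pairs[pair_row, ]
      expect_true(any(vapply(dup_groups, function(g) all(pair %in% g),
                             logical(1))))
    }
    expect_true(all(lengths(dup_groups) == 2))  # no false merges
  }
})

test_that("dosage concordance recovers exact, null and calibrated cases", {
  set.seed(60)
  calls <- matrix(rbinom(50 * 80, 2, 0.4), 50, 80,
                  dimnames = list(NULL, paste0("s", 1:80)))
  truth <- make_gt(calls)
  exact <- make_gt(calls, dosage = calls + 0.0)
  dc <- dosage_concordance(exact, truth)
  expect_true(all(abs(dc$per_variant$r2 - 1) < 1e-12))
  # independent dosages: median r2 near zero
  indep <- make_gt(calls, dosage = matrix(runif(50 * 80, 0, 2), 50, 80,
                                          dimnames = dimnames(calls)))
  dc0 <- dosage_concordance(indep, truth)
  expect_lt(median(dc0$per_variant$r2), 0.05)
  # zero-variance truth variants are skipped and counted
  calls2 <- calls; calls2[1, ] <- 1L
  truth2 <- make_gt(calls2)
  dc2 <- dosage_concordance(indep, truth2)
  expect_equal(dc2$n_skipped, 1L)
})
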