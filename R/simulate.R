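#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The generator
#' emulates the outputs of an RNA-seq genotyping pipeline (caller +
#' imputation), a gene-level counter, and an allelic read-count extractor,
#' with the statistical structure the downstream analyses assume.
#'
#' @param n_samples named integer vector: samples per population
#'   (e.g. `c(EUR = 100, AFR = 50, ASN = 50)`).
#' @param n_studies number of contributing studies; samples are assigned
#'   round-robin and each study carries one tissue label.
#' @param n_genes,n_variants numbers of genes and biallelic SNPs, all placed
#'   uniformly on a single chromosome of length `chrom_length`.
#' @param chrom_length simulated chromosome length in bp.
#' @param mean_depth mean read depth, both for genotype support and for
#'   allelic counts at heterozygous sites.
#' @param eqtl_frac fraction of genes given a planted cis effect.
#' @param eqtl_beta per-allele effect size of planted eQTLs, in units of the
#'   residual SD of log2 expression.
#' @param ase_frac fraction of variants given planted allelic imbalance.
#' @param ase_ratio true alternative-allele read proportion at planted sites.
#' @param ref_bias multiplicative sampling bias toward the reference allele
#'   in \[0, 1\]: alt reads are sampled with relative weight `1 - ref_bias`.
#' @param dup_pairs number of planted duplicate sample pairs (identical hard
#'   calls, independent dosage noise and depths).
#' @param contaminated number of planted 1:1 two-sample mixtures (these show
#'   grossly elevated heterozygosity).
#' @param imputation_dr2 mean target dosage r-squared; per-variant targets
#'   are drawn from a Beta distribution with this mean (concentration 30)
#'   unless `dr2_spread = FALSE`, and the dosage noise is calibrated so the
#'   realized squared correlation with the true genotype matches.
#' @param dr2_spread logical; FALSE gives every variant exactly
#'   `imputation_dr2`.
#' @param study_sd SD of per-study, per-gene baseline shifts (log2 scale).
#' @param sex_genes logical; append an XIST-like chrX gene and `n_chry_genes`
#'   chrY genes with sex-linked expression.
#' @param n_chry_genes number of chrY marker genes when `sex_genes` is TRUE.
#' @param couple_ase_eqtl logical; plant allelic imbalance at the planted
#'   eQTL variants with the direction matching the eQTL effect sign (for
#'   joint eQTL/ASE direction studies) instead of at random sites.
#' @param seed integer; fully determines all generated tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(EUR = 100, AFR = 50, ASN = 50),
                       n_studies = 4,
                       n_genes = 300,
                       n_variants = 1000,
                       chrom_length = 1e7,
                       mean_depth = 30,
                       eqtl_frac = 0.1,
                       eqtl_beta = 1,
                       ase_frac = 0.1,
                       ase_ratio = 0.7,
                       ref_bias = 0,
                       dup_pairs = 0,
                       contaminated = 0,
                       imputation_dr2 = 0.9,
                       dr2_spread = TRUE,
                       study_sd = 0.5,
                       sex_genes = TRUE,
                       n_chry_genes = 5,
                       couple_ase_eqtl = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(cfg$eqtl_frac, cfg$ase_frac, cfg$ase_ratio, cfg$ref_bias)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$imputation_dr2 <= 0 || cfg$imputation_dr2 > 1)
    stop("imputation_dr2 must lie in (0, 1]")
  if (is.null(names(cfg$n_samples))) stop("n_samples must be named by population")
  if (any(cfg$n_samples < 2)) stop("need at least 2 samples per population")
  class(cfg) <- "sim_config"
  cfg
}

# truncated Beta(0.5, 0.5): a U-shaped site-frequency spectrum restricted to
# common variation, so most sites survive a MAF >= 0.05 filter
rfreq <- function(n, lo = 0.05, hi = 0.95) {
  stats::qbeta(stats::runif(n, stats::pbeta(lo, 0.5, 0.5),
                            stats::pbeta(hi, 0.5, 0.5)), 0.5, 0.5)
}

# Gaussian dosage noise at the sd implied by the target r2, clipped to
# [0, 2]; clipping shrinks the realized noise, so one recalibration pass
# rescales the sd using the realized squared correlation.
noisy_dosage <- function(g, r2_target) {
  n <- length(g)
  v <- stats::var(g, na.rm = TRUE)
  gm <- mean(g, na.rm = TRUE)
  gfill <- ifelse(is.na(g), gm, g)
  if (r2_target >= 1 || is.na(v) || v == 0)
    return(pmin(2, pmax(0, gfill)))
  s0 <- sqrt(v * (1 - r2_target) / r2_target)
  d0 <- pmin(2, pmax(0, gfill + stats::rnorm(n, 0, s0)))
  r2a <- suppressWarnings(stats::cor(d0[!is.na(g)], g[!is.na(g)])^2)
  s1 <- if (is.na(r2a) || r2a <= r2_target || r2a >= 1) s0 else
    s0 * sqrt(r2a * (1 - r2_target) / (r2_target * (1 - r2a)))
  pmin(2, pmax(0, gfill + stats::rnorm(n, 0, s1)))
}

#' Simulate imputed genotypes and a sample sheet
#'
#' Per population, per-variant allele frequencies are drawn independently
#' from a truncated U-shaped spectrum (so populations separate in genotype
#' PCA) and genotypes follow Hardy-Weinberg proportions. Read depths are
#' Poisson with variant-level rate heterogeneity; genotype quality grows
#' with depth and calls with fewer than 2 supporting reads are missing.
#' Dosages are the true genotype plus Gaussian noise calibrated so that the
#' squared correlation with truth matches the per-variant target dosage
#' r-squared. Duplicate pairs share hard calls but have independent noise;
#' contaminated samples are 1:1 mixtures of two genotype vectors, called
#' heterozygous whenever the pooled four allele copies are mixed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_data` with elements `genotypes`
#'   ([genotype_table()]), `sheet` ([sample_sheet()]) and `truth` (list with
#'   `freqs`, `true_calls`, `duplicate_pairs`, `contaminated`, `sex`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- rep(names(cfg$n_samples), cfg$n_samples)
  n <- length(pops)
  ids <- sprintf("S%04d", seq_len(n))
  study <- sprintf("study%02d", (seq_len(n) - 1L) %% cfg$n_studies + 1L)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sheet <- sample_sheet(data.frame(
    sample_id = ids, study_id = study, population = pops,
    tissue = sprintf("tissue%02d", match(study, sort(unique(study)))),
    is_reference_set = study == "study01",
    annotated_sex = sex,
    n_expressed_genes = NA_integer_,
    stringsAsFactors = FALSE
  ))

  nv <- cfg$n_variants
  pos <- sort(sample.int(cfg$chrom_length, nv))
  freqs <- sapply(names(cfg$n_samples), function(p) rfreq(nv))
  freqs <- matrix(freqs, nrow = nv,
                  dimnames = list(NULL, names(cfg$n_samples)))
  calls <- matrix(NA_integer_, nv, n, dimnames = list(NULL, ids))
  for (p in names(cfg$n_samples)) {
    cols <- which(pops == p)
    calls[, cols] <- stats::rbinom(nv * length(cols), 2L, freqs[, p])
  }

  # planted contaminated samples: 1:1 mixture of the sample's own genotype
  # and a random partner; 4 pooled allele copies, het unless all-ref/all-alt
  contam <- character(0)
  if (cfg$contaminated > 0) {
    if (cfg$contaminated >= n) stop("too many contaminated samples requested")
    cidx <- seq(n, n - cfg$contaminated + 1L)
    contam <- ids[cidx]
    for (i in cidx) {
      partner <- sample(setdiff(seq_len(n), cidx), 1)
      k <- calls[, i] + calls[, partner]
      calls[, i] <- ifelse(k == 0L, 0L, ifelse(k == 4L, 2L, 1L))
    }
  }

  # planted duplicate pairs: identical hard calls, everything else redrawn
  dup_pairs <- NULL
  if (cfg$dup_pairs > 0) {
    avail <- setdiff(seq_len(n), match(contam, ids))
    if (length(avail) < 2 * cfg$dup_pairs) stop("not enough samples for dup_pairs")
    picked <- sample(avail, 2 * cfg$dup_pairs)
    dup_pairs <- matrix(ids[picked], ncol = 2, byrow = TRUE)
    for (r in seq_len(cfg$dup_pairs)) {
      a <- picked[2 * r - 1]; b <- picked[2 * r]
      calls[, b] <- calls[, a]
      sheet$study_id[b] <- sheet$study_id[a]
      sheet$tissue[b] <- sheet$tissue[a]
      sheet$population[b] <- sheet$population[a]
      sheet$is_reference_set[b] <- FALSE
      sheet$annotated_sex[b] <- sheet$annotated_sex[a]
    }
  }

  site_rate <- stats::rgamma(nv, shape = 4, scale = cfg$mean_depth / 4)
  depth <- matrix(stats::rpois(nv * n, rep(site_rate, n)), nv, n,
                  dimnames = list(NULL, ids))
  gq <- pmin(depth * 3, 99)
  true_calls <- calls
  calls[depth < 2] <- NA_integer_

  dr2_target <- if (cfg$dr2_spread && cfg$imputation_dr2 < 1) {
    k <- 30
    stats::rbeta(nv, cfg$imputation_dr2 * k, (1 - cfg$imputation_dr2) * k)
  } else rep(cfg$imputation_dr2, nv)

  dosage <- matrix(0, nv, n, dimnames = list(NULL, ids))
  for (v in seq_len(nv))
    dosage[v, ] <- noisy_dosage(calls[v, ], dr2_target[v])

  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(nv)),
    chrom = "1", pos = pos,
    ref_allele = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    alt_allele = NA_character_, dr2 = dr2_target,
    stringsAsFactors = FALSE
  )
  variants$alt_allele <- vapply(variants$ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))

  gt <- genotype_table(variants, calls, gq = gq, dosage = dosage,
                       depth = depth)
  structure(
    list(genotypes = gt, sheet = sheet,
         truth = list(freqs = freqs, true_calls = true_calls,
                      duplicate_pairs = dup_pairs, contaminated = contam,
                      sex = stats::setNames(sex, ids))),
    class = "sim_data"
  )
}

#' Simulate a gene-level count matrix with planted cis effects
#'
#' Log2-scale expression is a per-gene baseline plus a per-study shift, a
#' GC-by-sample technical term, the planted cis effect (`eqtl_beta` times
#' the sample's dosage at the gene's assigned variant) and unit Gaussian
#' noise; the result is exponentiated, scaled by a lognormal library-size
#' factor and Poisson-sampled to counts. Planted genes are paired with the
#' nearest variant within 250 kb of the gene center; when no variant is
#' that close the gene is relocated next to one, so planted pairs always
#' exist. When `cfg$sex_genes` is TRUE an XIST-like chrX gene and several
#' chrY genes with sex-linked expression are appended.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genotypes()]; its `truth` element is
#'   extended with `eqtl` (planted gene/variant/beta) and the sheet's
#'   `n_expressed_genes` is filled in.
#' @return `sim`, with an `expression` element ([expression_matrix()]) added.
#' @export
simulate_expression <- function(cfg, sim) {
  stopifnot(inherits(sim, "sim_data"))
  set.seed(cfg$seed + 1000L)
  gt <- sim$genotypes
  n <- length(gt$samples)
  ng <- cfg$n_genes
  center <- sort(sample.int(cfg$chrom_length, ng))
  width <- sample(2000:50000, ng, replace = TRUE)

  n_eqtl <- round(cfg$eqtl_frac * ng)
  eqtl_genes <- if (n_eqtl > 0) sort(sample.int(ng, n_eqtl)) else integer(0)
  eqtl_var <- integer(0); eqtl_beta <- numeric(0)
  for (g in eqtl_genes) {
    d <- abs(gt$variants$pos - center[g])
    j <- which.min(d)
    if (d[j] > 250000) {
      # co-place: move the gene next to a variant so the cis pair exists
      center[g] <- gt$variants$pos[j] + sample(-100000:100000, 1)
      center[g] <- max(1L, min(cfg$chrom_length, center[g]))
    }
    eqtl_var <- c(eqtl_var, j)
    eqtl_beta <- c(eqtl_beta, cfg$eqtl_beta * sample(c(-1, 1), 1))
  }

  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(ng)),
    chrom = "1",
    start = pmax(1L, as.integer(center - width %/% 2)),
    end = as.integer(center + width %/% 2),
    gc_fraction = stats::runif(ng, 0.35, 0.65),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rnorm(ng, 5, 1.5)
  studies <- sim$sheet$study_id
  ustudy <- sort(unique(studies))
  study_shift <- matrix(stats::rnorm(ng * length(ustudy), 0, cfg$study_sd),
                        ng, length(ustudy), dimnames = list(NULL, ustudy))
  gc_coef <- stats::rnorm(n, 0, 0.5)
  gcz <- as.numeric(scale(genes$gc_fraction))
  libsize <- exp(stats::rnorm(n, 0, 0.3))

  mu <- matrix(baseline, ng, n) + study_shift[, studies] +
    outer(gcz, gc_coef) + matrix(stats::rnorm(ng * n), ng, n)
  if (n_eqtl > 0) {
    dos <- gt$dosage[eqtl_var, , drop = FALSE]
    mu[eqtl_genes, ] <- mu[eqtl_genes, ] + dos * eqtl_beta
  }
  lambda <- sweep(2^mu, 2, libsize, `*`)
  counts <- matrix(stats::rpois(ng * n, lambda), ng, n,
                   dimnames = list(NULL, gt$samples))

  if (isTRUE(cfg$sex_genes)) {
    sexes <- sim$truth$sex[gt$samples]
    female <- sexes == "female"
    xist <- stats::rnorm(n, ifelse(female, 7, 1), 0.5)
    sexg <- data.frame(
      gene_id = c("XIST", sprintf("chrY_gene%02d", seq_len(cfg$n_chry_genes))),
      chrom = c("X", rep("Y", cfg$n_chry_genes)),
      start = 1000000L + 100000L * seq_len(cfg$n_chry_genes + 1L),
      end = 1010000L + 100000L * seq_len(cfg$n_chry_genes + 1L),
      gc_fraction = 0.5, stringsAsFactors = FALSE
    )
    ymu <- matrix(stats::rnorm(cfg$n_chry_genes * n,
                               rep(ifelse(female, 0.3, 6), each = cfg$n_chry_genes),
                               0.5), cfg$n_chry_genes, n)
    sexcounts <- rbind(stats::rpois(n, 2^xist),
                       matrix(stats::rpois(cfg$n_chry_genes * n, 2^ymu),
                              cfg$n_chry_genes, n))
    colnames(sexcounts) <- gt$samples
    genes <- rbind(genes, sexg)
    counts <- rbind(counts, sexcounts)
  }

  expr <- expression_matrix(genes, counts, counts = TRUE)
  sim$expression <- expr
  sim$sheet$n_expressed_genes <- as.integer(colSums(counts > 0))
  sim$truth$eqtl <- data.frame(
    gene_id = genes$gene_id[eqtl_genes],
    variant_id = gt$variants$variant_id[eqtl_var],
    beta = eqtl_beta, stringsAsFactors = FALSE
  )
  sim
}

#' Simulate allelic read counts at heterozygous sites
#'
#' For every (variant, sample) pair called heterozygous, a total read count
#' is drawn Poisson with mean `cfg$mean_depth` and the alternative-allele
#' count Binomial with probability 0.5 (null sites) or `cfg$ase_ratio`
#' (planted sites), shifted toward the reference allele when
#' `cfg$ref_bias > 0` (alt reads sampled with relative weight
#' `1 - ref_bias`).
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genotypes()] (or later stage); its `truth`
#'   gains `ase_sites` (variant_id, true alt proportion).
#' @return `sim`, with an `allelic_counts` element added.
#' @export
simulate_allelic_counts <- function(cfg, sim) {
  stopifnot(inherits(sim, "sim_data"))
  set.seed(cfg$seed + 2000L)
  gt <- sim$genotypes
  nv <- nrow(gt$variants)

  if (isTRUE(cfg$couple_ase_eqtl) && !is.null(sim$truth$eqtl) &&
      nrow(sim$truth$eqtl) > 0) {
    idx <- match(unique(sim$truth$eqtl$variant_id), gt$variants$variant_id)
    beta <- sim$truth$eqtl$beta[match(gt$variants$variant_id[idx],
                                      sim$truth$eqtl$variant_id)]
    p_true <- ifelse(beta > 0, cfg$ase_ratio, 1 - cfg$ase_ratio)
  } else {
    n_ase <- round(cfg$ase_frac * nv)
    idx <- if (n_ase > 0) sort(sample.int(nv, n_ase)) else integer(0)
    p_true <- rep(cfg$ase_ratio, length(idx))
  }
  p_site <- rep(0.5, nv)
  p_site[idx] <- p_true

  het <- which(gt$calls == 1L, arr.ind = TRUE)
  vid <- gt$variants$variant_id[het[, 1]]
  p <- p_site[het[, 1]]
  if (cfg$ref_bias > 0)
    p <- p * (1 - cfg$ref_bias) / (1 - p * cfg$ref_bias)
  total <- stats::rpois(nrow(het), cfg$mean_depth)
  alt <- stats::rbinom(nrow(het), total, p)
  df <- data.frame(
    variant_id = vid,
    chrom = gt$variants$chrom[het[, 1]],
    pos = gt$variants$pos[het[, 1]],
    sample_id = gt$samples[het[, 2]],
    ref_count = total - alt,
    alt_count = alt,
    in_excluded_region = FALSE,
    mappability = 1.0,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$pos, df$sample_id), ]
  rownames(df) <- NULL
  class(df) <- c("allelic_count_table", class(df))
  sim$allelic_counts <- df
  sim$truth$ase_sites <- data.frame(
    variant_id = gt$variants$variant_id[idx],
    alt_proportion = p_true, stringsAsFactors = FALSE
  )
  sim
}

#' Generate a complete simulated input bundle
#'
#' Runs the three generators and writes the pipeline's input files to a
#' directory: `genotypes.vcf`, `expression.tsv`, `allelic_counts.tsv`,
#' `sample_sheet.tsv`, exclusion and mappability BEDs (a small random subset
#' of sites is marked excluded / low-mappability, exercising the BED
#' boundary conventions), and `truth.json` with the planted ground truth.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @return The `sim_data` object, invisibly.
#' @export
simulate_bundle <- function(cfg, dir) {
  sim <- simulate_genotypes(cfg)
  sim <- simulate_expression(cfg, sim)
  sim <- simulate_allelic_counts(cfg, sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_allelic_counts(sim$allelic_counts, file.path(dir, "allelic_counts.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"))

  set.seed(cfg$seed + 3000L)
  v <- sim$genotypes$variants
  nx <- max(1L, round(0.02 * nrow(v)))
  excl <- sort(sample.int(nrow(v), nx))
  lowmap <- sort(sample(setdiff(seq_len(nrow(v)), excl), nx))
  # BED: 0-based half-open; a 1-based position p is the interval [p-1, p)
  utils::write.table(
    data.frame(v$chrom[excl], v$pos[excl] - 1L, v$pos[excl]),
    file.path(dir, "exclusions.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(v$chrom[lowmap], v$pos[lowmap] - 1L, v$pos[lowmap],
               "lowmap", 0.5),
    file.path(dir, "mappability.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(duplicate_pairs = sim$truth$duplicate_pairs,
         contaminated = sim$truth$contaminated,
         eqtl = sim$truth$eqtl, ase_sites = sim$truth$ase_sites,
         sex = as.list(sim$truth$sex)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
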