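# Small in-code fixtures shared across tests.

# genotype table built directly from a call matrix (variants x samples)
make_gt <- function(calls, dr2 = NULL, pos = NULL, gq = NULL, dosage = NULL,
                    depth = NULL, chrom = "1") {
  nv <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(nv) * 1000L
  variants <- data.frame(
    variant_id = sprintf("v%03d", seq_len(nv)),
    chrom = chrom, pos = as.integer(pos),
    ref_allele = "A", alt_allele = "G",
    stringsAsFactors = FALSE
  )
  if (!is.null(dr2)) variants$dr2 <- dr2
  genotype_table(variants, calls, gq = gq, dosage = dosage, depth = depth)
}

# expression matrix with evenly spaced genes on one chromosome
make_expr <- function(values, centers = NULL, chrom = "1", counts = FALSE,
                      gc = 0.5) {
  ng <- nrow(values)
  if (is.null(centers)) centers <- seq_len(ng) * 10000L
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(ng)),
    chrom = chrom,
    start = as.integer(centers - 500L), end = as.integer(centers + 500L),
    gc_fraction = gc, stringsAsFactors = FALSE
  )
  expression_matrix(genes, values, counts = counts)
}

# minimal VCF text written to a temp file; body rows are full records
write_vcf_fixture <- function(body, samples = c("s1", "s2", "s3"),
                              format = "GT:GQ") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

# independent TMM oracle: the published trimmed-mean-of-M-values definition
# written out directly (reference by upper quartile, doubly trimmed,
# inverse-variance weighted), for cross-checking the package's factors
tmm_oracle <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(j) {
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    no <- lib[j]; nr <- lib[ref]
    m <- log2((o / no) / (r / nr))
    a <- 0.5 * log2((o / no) * (r / nr))
    w <- 1 / ((no - o) / (no * o) + (nr - r) / (nr * r))  # inverse variance
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# independent binomial LRT oracle via dbinom
lrt_oracle <- function(ref, alt) {
  a <- sum(alt); tot <- sum(ref) + a
  p <- a / tot
  2 * (sum(stats::dbinom(alt, ref + alt, p, log = TRUE)) -
         sum(stats::dbinom(alt, ref + alt, 0.5, log = TRUE)))
}

# brute-force BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
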