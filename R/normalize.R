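#' Quantile-normalize an expression matrix
#'
#' Forces every sample to the same distribution: each sample's sorted value
#' vector becomes the cross-sample mean of sorted vectors, ties within a
#' sample receiving the mean of the quantile values they span. Implemented
#' with [limma::normalizeQuantiles()].
#'
#' @param expr an [expression_matrix()].
#' @return An [expression_matrix()] of normalized values (`counts = FALSE`).
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  zero <- colSums(abs(v)) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(v)[zero], collapse = ", "))
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  expression_matrix(expr$genes, out, counts = FALSE,
                    total_mapped_reads = expr$total_mapped_reads)
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Between-sample normalization factors for raw counts: per sample, the
#' exponentiated precision-weighted mean of gene-wise log2 count ratios
#' against a reference sample, after trimming the most extreme fractions by
#' log-ratio (M) and by average abundance (A). The reference is the sample
#' whose upper quartile (of counts scaled by library size) is closest to the
#' mean upper quartile; genes with a zero count in either sample are
#' excluded; factors are rescaled so their geometric mean is exactly 1.
#' Implemented with [edgeR::calcNormFactors()].
#'
#' @param expr an [expression_matrix()] of raw counts.
#' @param trim_m trimmed fraction of the M distribution, each tail
#'   (default 0.3).
#' @param trim_a trimmed fraction of the A distribution, each tail
#'   (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(expr, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!expr$counts) stop("TMM factors require raw counts")
  f <- edgeR::calcNormFactors(expr$values, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (any(!is.finite(f)))
    stop("TMM factor undefined (a sample shares no nonzero genes with the reference)")
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(expr$values))
}

#' Log2-transform, center and scale an expression matrix
#'
#' Each cell becomes `log2(x / factor + offset)`; each gene row is then
#' centered to mean 0 and scaled to SD 1. Zero-variance genes cannot be
#' scaled and are dropped with a message. The default per-sample factor is
#' the TMM-adjusted relative library size (library size times TMM factor,
#' divided by its geometric mean), so values stay on a count-like scale.
#'
#' @param expr an [expression_matrix()] of raw counts (or non-negative
#'   values).
#' @param factors per-sample divisors; NULL for TMM-adjusted relative
#'   library sizes, or 1 to skip depth scaling.
#' @param offset pseudocount added before the log (default 1).
#' @return A centered/scaled [expression_matrix()] (`counts = FALSE`).
#' @export
log_center_scale <- function(expr, factors = NULL, offset = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (any(v < 0)) stop("values must be non-negative")
  if (is.null(factors)) {
    eff <- colSums(v) * tmm_factors(expr)
    factors <- eff / exp(mean(log(eff)))
  }
  if (length(factors) == 1) factors <- rep(factors, ncol(v))
  lv <- log2(sweep(v, 2, factors, `/`) + offset)
  sds <- apply(lv, 1, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) dropped")
  lv <- lv[keep, , drop = FALSE]
  out <- t(scale(t(lv)))
  dimnames(out) <- dimnames(lv)
  expression_matrix(expr$genes[keep, , drop = FALSE], out, counts = FALSE,
                    total_mapped_reads = expr$total_mapped_reads)
}

#' Regress covariates (and optionally expression PCs) out of expression
#'
#' Per gene, ordinary-least-squares residuals after projecting out an
#' intercept plus the supplied sample-level covariates. When `n_pcs > 0`,
#' principal components are computed on the covariate-corrected matrix and
#' projected out in a second pass (the standard way hidden expression
#' confounders are removed before eQTL mapping).
#'
#' @param expr an [expression_matrix()] (normalized).
#' @param covariates data.frame or matrix, one row per sample in column
#'   order of `expr` (e.g. total mapped reads, GC summary, genotype PCs);
#'   NULL for none.
#' @param n_pcs number of expression PCs to remove (capped at
#'   `min(n_samples, n_genes) - 1`).
#' @return A residual [expression_matrix()].
#' @export
regress_covariates <- function(expr, covariates = NULL, n_pcs = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  y <- t(expr$values)                    # samples x genes
  n <- nrow(y)
  resid <- y
  if (!is.null(covariates)) {
    x <- as.matrix(covariates)
    if (nrow(x) != n) stop("covariates must have one row per sample")
    xm <- cbind(intercept = 1, x)
    qx <- qr(xm)
    if (qx$rank < ncol(xm)) {
      cc <- suppressWarnings(stats::cor(x))
      diag(cc) <- 0
      bad <- which(abs(cc) > 0.999, arr.ind = TRUE)
      pair <- if (nrow(bad)) paste(colnames(x)[bad[1, ]], collapse = " ~ ")
              else "an intercept-confounded column"
      stop("collinear covariates: ", pair)
    }
    resid <- qr.resid(qx, y)
  } else {
    resid <- scale(y, center = TRUE, scale = FALSE)
  }
  if (n_pcs > 0) {
    k <- min(n_pcs, n - 1L, ncol(resid) - 1L)
    pc <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    resid <- qr.resid(qr(cbind(1, scores)), resid)
  }
  out <- t(resid)
  dimnames(out) <- dimnames(expr$values)
  expression_matrix(expr$genes, out, counts = FALSE,
                    total_mapped_reads = expr$total_mapped_reads)
}

#' Run the full normalization recipe for eQTL mapping
#'
#' TMM scaling, log2 with pseudocount, per-gene centering/scaling, then OLS
#' removal of sample-level covariates (total mapped reads, per-sample mean
#' GC of expressed genes, genotype PCs) and of leading expression PCs. The
#' number of expression PCs defaults to `min(100, floor(n_samples / 4))` so
#' small cohorts keep degrees of freedom; pass `n_expr_pcs` explicitly for
#' the full-scale setting.
#'
#' @param expr raw-count [expression_matrix()].
#' @param genotype_pcs optional samples x k matrix of genotype PCs.
#' @param n_expr_pcs expression PCs to remove (NULL for the default rule).
#' @param offset pseudocount for the log (default 1).
#' @return List with `residuals` ([expression_matrix()]), `tmm` (factors),
#'   and `recipe` (ordered record of the steps applied).
#' @export
normalize_for_eqtl <- function(expr, genotype_pcs = NULL, n_expr_pcs = NULL,
                               offset = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- ncol(expr$values)
  if (is.null(n_expr_pcs)) n_expr_pcs <- min(100L, n %/% 4L)
  tmm <- tmm_factors(expr)
  lcs <- log_center_scale(expr, offset = offset)
  gc_mean <- as.numeric(crossprod(expr$genes$gc_fraction,
                                  expr$values) / colSums(expr$values))
  covs <- data.frame(total_reads = expr$total_mapped_reads,
                     gc_mean = gc_mean)
  if (!is.null(genotype_pcs)) {
    gp <- as.matrix(genotype_pcs)
    colnames(gp) <- paste0("geno_pc", seq_len(ncol(gp)))
    covs <- cbind(covs, gp)
  }
  resid <- regress_covariates(lcs, covariates = covs, n_pcs = n_expr_pcs)
  list(residuals = resid, tmm = tmm,
       recipe = list(steps = c("tmm", sprintf("log2(offset=%g)", offset),
                               "center_scale",
                               paste0("regress_covariates(",
                                      paste(colnames(covs), collapse = ","), ")"),
                               sprintf("remove_pcs(%d)", n_expr_pcs))))
}
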