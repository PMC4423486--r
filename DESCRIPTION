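Package: rnaqtl
Title: Genotype Quality Control, cis-eQTL Meta-Analysis and Allele-Specific
    Expression from RNA-seq-Derived Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical core of a pipeline that derives genotypes from
    RNA-seq data and uses them for expression genetics. Provides sample
    quality control (expression-PCA outliers, heterozygosity-rate filters,
    sex-annotation checks), duplicate-sample detection by pairwise genotype
    concordance on LD-pruned high-quality variants, expression normalization
    (quantile, TMM, covariate and principal-component regression),
    population-stratified cis-eQTL mapping with sqrt(n)-weighted z-score
    meta-analysis and study-stratified permutation false discovery rates,
    and a per-SNP binomial likelihood-ratio test for allele-specific
    expression. A synthetic-data generator emulates aligner and caller
    outputs (Hardy-Weinberg genotypes across populations, imputation noise
    calibrated to a target dosage r-squared, negative-binomial-like counts
    with planted cis effects, binomial allelic counts with planted imbalance,
    planted duplicate and contaminated samples) so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    limma,
    edgeR,
    igraph,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
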