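test_that("filter_snps uses a strict threshold and preserves order", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = 1:3, allele_ref = "A", allele_alt = "G",
                     pvalue = c(1e-9, 5e-8, 4e-8), effect = 0)
  kept <- filter_snps(snps)
  expect_equal(kept$snp_id, c("a", "c"))   # boundary 5e-8 excluded

  expect_equal(nrow(filter_snps(snps[0, ])), 0)

  # count matches a linear scan on simulated data with planted loci
  genes <- simulate_gene_models(20)
  loci <- data.frame(gene_id = c("G00002", "G00010"), n_snps = c(7L, 5L),
                     scale = c(12, 10))
  sim <- simulate_gwas(genes, 500, loci, seed = 8)
  expect_equal(nrow(filter_snps(sim)), sum(sim$pvalue < 5e-8))
  expect_gte(nrow(filter_snps(sim)), 12)
})

test_that("map_snps_to_genes: inclusive window, multi-mapping, brute-force oracle", {
  genes <- data.frame(gene_id = c("GA", "GB"), symbol = c("A", "B"),
                      chrom = c("chr1", "chr1"),
                      start = c(50000L, 58000L), end = c(55000L, 63000L),
                      strand = "+")
  mk <- function(pos) data.frame(snp_id = paste0("s", seq_along(pos)),
                                 chrom = "chr1", pos = as.integer(pos),
                                 allele_ref = "A", allele_alt = "G",
                                 pvalue = 0.5, effect = 0)
  w <- 10000L
  # at gene start: mapped; at start - w: mapped; at start - w - 1: not
  m <- map_snps_to_genes(mk(c(50000, 40000, 39999)), genes, w)
  expect_true(all(c("s1", "s2") %in% m$snp_id))
  expect_false("s3" %in% m$snp_id)
  # a SNP in the overlap of both windows maps to both genes
  m2 <- map_snps_to_genes(mk(54000), genes, w)
  expect_equal(sort(m2$gene_id), c("GA", "GB"))

  # random fixture vs quadratic all-pairs oracle
  set.seed(42)
  g2 <- simulate_gene_models(20)
  snps <- mk(sample(1:2e6, 200))
  snps$chrom <- sample(unique(g2$chrom), 200, replace = TRUE)
  got <- map_snps_to_genes(snps, g2, w)
  want <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    hits <- g2[g2$chrom == snps$chrom[i] &
                 g2$start - w <= snps$pos[i] & snps$pos[i] <= g2$end + w, ]
    if (nrow(hits) == 0) return(NULL)
    data.frame(snp_id = snps$snp_id[i], gene_id = hits$gene_id)
  }))
  key <- function(d) sort(paste(d$snp_id, d$gene_id))
  expect_equal(key(got), key(want))
})

test_that("gene_level_pvalue: Fisher identities and chi-square oracle", {
  # k = 1 identity
  expect_equal(gene_level_pvalue(0.03)$pvalue, 0.03, tolerance = 1e-12)
  # all ones
  r <- gene_level_pvalue(c(1, 1, 1))
  expect_equal(r$stat, 0)
  expect_equal(r$pvalue, 1)
  # frozen example: p = rep(0.05, 3)
  r2 <- gene_level_pvalue(rep(0.05, 3))
  expect_equal(r2$stat, -2 * 3 * log(0.05), tolerance = 1e-12)
  expect_equal(round(r2$stat, 4), 17.9744)
  expect_equal(r2$df, 6)
  expect_equal(r2$pvalue, oracle_chisq_upper(r2$stat, 6), tolerance = 1e-10)

  expect_error(gene_level_pvalue(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(gene_level_pvalue(rep(0.1, 3), ld = diag(2)), "2x2")
})

test_that("Brown's method: identity LD equals Fisher; correlation widens tails", {
  p <- c(0.01, 0.2, 0.6, 0.05)
  fisher <- gene_level_pvalue(p)
  brown_id <- gene_level_pvalue(p, ld = diag(4))
  expect_equal(brown_id$pvalue, fisher$pvalue, tolerance = 1e-12)
  expect_equal(brown_id$df, fisher$df, tolerance = 1e-12)

  ld <- matrix(0.8, 4, 4); diag(ld) <- 1
  brown <- gene_level_pvalue(p, ld = ld)
  expect_gt(brown$pvalue, fisher$pvalue)   # positive LD is less informative
  expect_lt(brown$df, fisher$df)
  expect_equal(brown$pvalue,
               oracle_chisq_upper(brown$stat / brown$scale, brown$df),
               tolerance = 1e-10)
})

test_that("combined p is monotone in each input", {
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(5, 0.01, 1)
    base <- gene_level_pvalue(p)$pvalue
    j <- sample(5, 1)
    p[j] <- p[j] / 2
    expect_lte(gene_level_pvalue(p)$pvalue, base)
  }
})

test_that("bonferroni_threshold matches the printed derivation", {
  expect_equal(signif(bonferroni_threshold(19081), 3), 2.62e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 0.0025)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("competitive enrichment: closed form, degenerate and null cases", {
  # constant statistic: beta 0, one-sided p = 0.5
  r <- enrich_competitive(rep(2, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(r$beta, 0)
  expect_equal(r$pvalue, 0.5)

  # members exactly 1 higher with equal within-group spread: beta = 1,
  # t matches a hand normal-equations computation on 6 genes
  y <- c(2.5, 3.5, 1.5, 2.5, 1.5, 2.5)
  memb <- c(1, 1, 0, 0, 0, 0)
  r2 <- enrich_competitive(y, memb)
  expect_equal(r2$beta, 1, tolerance = 1e-12)
  fit <- summary(stats::lm(y ~ memb))$coefficients
  expect_equal(r2$t, fit["memb", "t value"], tolerance = 1e-10)
  expect_equal(r2$se, fit["memb", "Std. Error"], tolerance = 1e-10)

  expect_error(enrich_competitive(1:6, rep(1, 6)), "members")

  # null calibration: p ~ Uniform under random membership (pooled seeds)
  ps <- unlist(lapply(1:10, function(s) {
    set.seed(s)
    y <- stats::rnorm(40)
    vapply(1:20, function(i) {
      enrich_competitive(y, sample(c(rep(1, 8), rep(0, 32))))$pvalue
    }, numeric(1))
  }))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("gene-property enrichment agrees with normal equations", {
  set.seed(9)
  y <- stats::rnorm(20); x <- stats::rnorm(20)
  r <- enrich_property(y, x)
  fit <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(r$beta, fit["x", "Estimate"], tolerance = 1e-10)
  expect_equal(r$se, fit["x", "Std. Error"], tolerance = 1e-10)

  # perfect fit: statistic = 2 x property
  r2 <- enrich_property(2 * x, x)
  expect_equal(r2$beta, 2, tolerance = 1e-10)
  expect_lt(r2$pvalue, 1e-12)

  # orthogonal property: |beta| < 3 se
  x2 <- x - sum(x * y) / sum(y^2) * y   # orthogonalized against y
  r3 <- enrich_property(y, x2)
  expect_lt(abs(r3$beta), 3 * r3$se)

  expect_error(enrich_property(y, rep(1, 20)), "zero-variance")
})

test_that("filter->map->aggregate recovers planted loci above the null median", {
  hits <- vapply(1:10, function(s) {
    genes <- simulate_gene_models(40)
    loci <- data.frame(gene_id = c("G00004", "G00022"), n_snps = 6L, scale = 10)
    snps <- simulate_gwas(genes, 800, loci, seed = s)
    res <- run_gwas_genes(snps, genes)
    gl <- res$gene_level
    planted <- gl$pvalue[gl$gene_id %in% loci$gene_id]
    all(planted < stats::median(gl$pvalue[!gl$gene_id %in% loci$gene_id]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
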