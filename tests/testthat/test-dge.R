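counts_fixture <- function(n_genes = 100, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = 50, size = 5),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("s%d", 1:n_samples)))
  storage.mode(m) <- "integer"
  m
}

test_that("filter_low_expression matches a direct per-gene scan", {
  m <- counts_fixture(100, 6)
  m[1, ] <- 0L                                   # all-zero gene removed
  m[2, ] <- 1L       # small but clearly above 1 CPM at these library sizes
  kept <- filter_low_expression(m, min_cpm = 1, min_samples = 3)
  expect_false("G001" %in% rownames(kept))
  expect_true("G002" %in% rownames(kept))

  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  want <- rownames(m)[rowSums(cpm > 1) >= 3]
  expect_equal(rownames(kept), want)

  m0 <- m; m0[, 2] <- 0L
  expect_error(filter_low_expression(m0), "s2")
})

test_that("TMM factors: identities, geometric mean 1, edgeR agreement", {
  m <- counts_fixture(300, 4, seed = 2)
  # identical libraries
  id <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  expect_equal(unname(tmm_factors(id)), rep(1, 3))
  # pure depth change: library 2x elementwise
  two <- cbind(a = m[, 1], b = 2L * m[, 1])
  expect_equal(unname(tmm_factors(two)), c(1, 1))

  # composition bias: 10% of genes 8-fold inflated in one sample
  biased <- m
  idx <- 1:30
  biased[idx, 2] <- biased[idx, 2] * 8L
  f <- tmm_factors(biased)
  # the inflated sample's factor moves below 1: its unaffected majority
  # of genes look depressed once the library total absorbs the inflation
  expect_lt(f[2], 1)
  # agreement with the independently implemented reference (edgeR)
  ref <- edgeR::calcNormFactors(biased, method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 1e-6)

  # geometric mean exactly 1 on random fixtures
  for (s in 1:5) {
    fs <- tmm_factors(counts_fixture(200, 5, seed = s))
    expect_equal(exp(mean(log(fs))), 1, tolerance = 1e-12)
  }
})

test_that("dge_test: antisymmetry, singular design, planted recovery", {
  sim <- simulate_counts(300, samples_per_arm = 8, seed = 4)
  res <- dge_test(sim$counts, sim$meta, c("age", "PMI"))
  expect_equal(nrow(res), 300)
  expect_true(all(res$p_adj >= res$pvalue - 1e-15))

  # relabeling diagnosis arms flips every logFC exactly
  meta_flip <- sim$meta
  meta_flip$diagnosis <- ifelse(meta_flip$diagnosis == "MDD", "control", "MDD")
  res_flip <- dge_test(sim$counts, meta_flip, c("age", "PMI"))
  expect_equal(res_flip$logFC, -res$logFC, tolerance = 1e-10)
  expect_equal(res_flip$pvalue, res$pvalue, tolerance = 1e-10)

  # confounded covariate is named
  meta_bad <- sim$meta
  meta_bad$bad <- as.numeric(meta_bad$diagnosis == "MDD")
  expect_error(dge_test(sim$counts, meta_bad, "bad"), "bad")

  # planted logFC = +2, n = 10 per arm: estimate within +/- 0.5 in >= 9/10 seeds
  ok <- vapply(1:10, function(s) {
    de <- data.frame(gene_id = "G00010", sex = "male", logfc = 2)
    sm <- simulate_counts(300, samples_per_arm = 10, sexes = "male",
                          planted_de = de, seed = s)
    r <- dge_test(sm$counts, sm$meta, c("age", "PMI", "pH", "RIN"))
    abs(r$logFC[r$gene_id == "G00010"] - 2) < 0.5
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("classify_degs applies strict inequalities at both thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    logFC = c(0.5, 1.2, -0.8),
                    pvalue = c(0.01, 1e-4, 0.04),
                    p_adj = c(0.04, 0.01, 0.2))
  got <- classify_degs(res)
  expect_equal(got$soft_deg, c(FALSE, TRUE, TRUE))   # |0.5| not > 0.5
  expect_equal(got$strict_deg, c(FALSE, TRUE, FALSE))
  expect_true(all(abs(got$logFC[got$strict_deg]) > 1))

  # random table vs direct re-evaluation
  set.seed(6)
  rt <- data.frame(gene_id = paste0("g", 1:200),
                   logFC = stats::rnorm(200, sd = 1),
                   pvalue = stats::runif(200))
  rt$p_adj <- bh_adjust(rt$pvalue)
  gt <- classify_degs(rt)
  expect_equal(gt$soft_deg, abs(rt$logFC) > 0.5 & rt$pvalue < 0.05)
  expect_equal(gt$strict_deg, abs(rt$logFC) > 1 & rt$p_adj < 0.05)
})

test_that("run_stratified: 2x2 design emits 4 tables, small strata skipped", {
  de <- data.frame(gene_id = c("G00007", "G00007"), sex = c("male", "female"),
                   logfc = c(2, -2))
  sim <- simulate_counts(400, samples_per_arm = 6, regions = c("BA9", "NAc"),
                         planted_de = de, seed = 5)
  out <- run_stratified(sim$counts, sim$meta, c("age", "PMI", "pH", "RIN"))
  expect_length(out$strata, 4)
  expect_equal(sort(out$summary$stratum), sort(names(out$strata)))

  # drop one arm to 1 sample in one stratum -> that stratum is skipped
  drop <- sim$meta$sample_id[sim$meta$sex == "male" & sim$meta$region == "BA9" &
                               sim$meta$diagnosis == "MDD"][-1]
  keep <- setdiff(sim$meta$sample_id, drop)
  expect_message(
    out2 <- run_stratified(sim$counts[, keep],
                           sim$meta[sim$meta$sample_id %in% keep, ],
                           c("age", "PMI")),
    "skipped")
  expect_length(out2$strata, 3)
})

test_that("direction_concordance joins TWAS and DGE and matches set logic", {
  twas <- data.frame(gene_id = c("G1", "G2", "G3"),
                     direction = c("up", "down", "up"),
                     meta_selected = c(TRUE, TRUE, FALSE))
  mk <- function(lfc, p) data.frame(gene_id = c("G1", "G2", "G3"),
                                    logFC = lfc, pvalue = p,
                                    p_adj = p, soft_deg = abs(lfc) > 0.5 & p < 0.05,
                                    strict_deg = FALSE)
  strata <- list(
    "D1.male.BA9" = mk(c(0.8, 0.9, 2), c(0.01, 0.01, 0.001)),
    "D1.female.BA9" = mk(c(-0.8, -0.9, 2), c(0.01, 0.01, 0.5)))
  cc <- direction_concordance(twas, strata)
  # G3 is not meta-selected: absent everywhere
  expect_false("G3" %in% cc$gene_id)
  male <- cc[cc$stratum == "D1.male.BA9", ]
  expect_equal(male$concordant[male$gene_id == "G1"], TRUE)    # up & +0.8
  expect_equal(male$concordant[male$gene_id == "G2"], FALSE)   # down & +0.9
  fem <- cc[cc$stratum == "D1.female.BA9", ]
  expect_equal(fem$concordant[fem$gene_id == "G1"], FALSE)     # up & -0.8
  expect_equal(fem$concordant[fem$gene_id == "G2"], TRUE)
  bs <- attr(cc, "by_sex")
  expect_equal(unname(bs["male"]), 0.5)
  expect_equal(unname(bs["female"]), 0.5)

  # overlap counts reproduce a direct set intersection on a random fixture
  set.seed(20)
  genes <- paste0("g", 1:50)
  tw2 <- data.frame(gene_id = genes,
                    direction = sample(c("up", "down"), 50, TRUE),
                    meta_selected = sample(c(TRUE, FALSE), 50, TRUE))
  st2 <- list("D.male.R" = data.frame(
    gene_id = genes, logFC = stats::rnorm(50), pvalue = stats::runif(50),
    p_adj = 1, soft_deg = sample(c(TRUE, FALSE), 50, TRUE), strict_deg = FALSE))
  cc2 <- direction_concordance(tw2, st2)
  want <- intersect(tw2$gene_id[tw2$meta_selected],
                    st2[[1]]$gene_id[st2[[1]]$soft_deg])
  expect_equal(sort(cc2$gene_id), sort(want))
})
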