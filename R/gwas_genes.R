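# Stage 1: SNP-level filtering, SNP-to-gene window mapping, gene-level
# p-value aggregation (Fisher, or Brown's correlated-chi-square
# approximation when an LD correlation matrix is supplied), a Bonferroni
# gene threshold, and MAGMA-style competitive / gene-property enrichment
# regression on the gene-level statistics.

#' Filter SNPs at a genome-wide significance threshold
#'
#' Keeps rows with `pvalue` strictly below `threshold`; input order is
#' preserved. This is the reporting path producing the significant-SNP
#' catalogue; gene-level aggregation uses all mapped SNPs.
#'
#' @param snps Data.frame of SNP records (see [read_summary_stats()]).
#' @param threshold Significance threshold, default `5e-8`.
#' @return The filtered data.frame.
#' @export
filter_snps <- function(snps, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  out <- snps[snps$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map SNPs to genes by position window
#'
#' A SNP maps to a gene when it lies on the same chromosome within the
#' gene body extended by `window_bp` on each side (inclusive bounds,
#' 1-based). A SNP may map to several genes; unmapped SNPs are absent
#' from the output.
#'
#' @param snps Data.frame of SNP records.
#' @param genes Data.frame of gene models.
#' @param window_bp Flank width in base pairs, default 10000.
#' @return Data.frame with columns `snp_id`, `gene_id`.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 10000L) {
  stopifnot(window_bp >= 0)
  if (nrow(snps) == 0 || nrow(genes) == 0) {
    return(data.frame(snp_id = character(0), gene_id = character(0)))
  }
  pieces <- lapply(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0 || nrow(s) == 0) return(NULL)
    lo <- g$start - window_bp
    hi <- g$end + window_bp
    hits <- lapply(seq_len(nrow(g)), function(i) {
      idx <- which(s$pos >= lo[i] & s$pos <= hi[i])
      if (length(idx) == 0) return(NULL)
      data.frame(snp_id = s$snp_id[idx], gene_id = g$gene_id[i])
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(data.frame(snp_id = character(0), gene_id = character(0)))
  out <- out[order(match(out$snp_id, snps$snp_id), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Combine SNP p-values into a gene-level p-value
#'
#' Without an LD matrix this is Fisher's method: the statistic
#' `-2 * sum(log(p))` is chi-square with `2k` degrees of freedom under
#' independence. With a correlation matrix, Brown's approximation is
#' used: the same statistic is referred to a scaled chi-square whose
#' scale and degrees of freedom come from the covariance of the
#' `-2 log p` terms implied by pairwise correlations (Kost & McDermott
#' polynomial approximation).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param ld Optional square symmetric correlation matrix with unit
#'   diagonal, one row/column per p-value.
#' @return List with `stat`, `df`, `pvalue` (and `scale` when `ld` is
#'   supplied).
#' @export
gene_level_pvalue <- function(pvalues, ld = NULL) {
  if (length(pvalues) == 0) stopf("no p-values supplied")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("all p-values must lie in (0, 1]")
  }
  k <- length(pvalues)
  stat <- -2 * sum(log(pvalues))
  if (is.null(ld)) {
    df <- 2 * k
    return(list(stat = stat, df = df,
                pvalue = stats::pchisq(stat, df = df, lower.tail = FALSE)))
  }
  ld <- as.matrix(ld)
  if (nrow(ld) != k || ncol(ld) != k) {
    stopf("LD matrix is %dx%d but %d p-values were given", nrow(ld), ncol(ld), k)
  }
  if (max(abs(ld - t(ld))) > 1e-8 || max(abs(diag(ld) - 1)) > 1e-8) {
    stopf("LD matrix must be symmetric with unit diagonal")
  }
  # cov(-2 log p_i, -2 log p_j) for correlated normal test statistics,
  # cubic polynomial fit in the correlation (Kost & McDermott 2002).
  e_stat <- 2 * k
  var_stat <- 4 * k
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      r <- ld[i, j]
      var_stat <- var_stat + 2 * (3.263 * r + 0.710 * r^2 + 0.027 * r^3)
    }
  }
  scale <- var_stat / (2 * e_stat)
  df <- 2 * e_stat^2 / var_stat
  list(stat = stat, df = df, scale = scale,
       pvalue = stats::pchisq(stat / scale, df = df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests (genes).
#' @param alpha Family-wise error rate, default 0.05.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    stopf("n_tests must be a single integer >= 1")
  }
  alpha / n_tests
}

ols_one_sided <- function(y, x, what) {
  if (stats::var(x) == 0) stopf("zero-variance %s", what)
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  resid <- yc - beta * xc
  df <- n - 2
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  t <- if (se == 0) {
    if (beta == 0) 0 else sign(beta) * Inf
  } else beta / se
  # one-sided (greater): is the mean gene statistic higher in the set /
  # does it increase with the property
  p <- stats::pt(t, df = df, lower.tail = FALSE)
  list(beta = beta, se = se, t = t, pvalue = p, df = df)
}

#' Competitive gene-set enrichment on gene-level statistics
#'
#' Ordinary least squares of the per-gene statistic (z or -log10 p) on a
#' set-membership indicator, one-sided test for a positive coefficient:
#' are member genes more associated than non-members?
#'
#' @param gene_stats Numeric vector of per-gene statistics.
#' @param membership Logical/0-1 vector, same length.
#' @return List with `beta`, `se`, `t`, `pvalue`, `df`.
#' @export
enrich_competitive <- function(gene_stats, membership) {
  membership <- as.numeric(membership)
  stopifnot(length(gene_stats) == length(membership))
  if (sum(membership == 1) < 2 || sum(membership == 0) < 2) {
    stopf("need >= 2 members and >= 2 non-members")
  }
  ols_one_sided(gene_stats, membership, "membership")
}

#' Gene-property enrichment on gene-level statistics
#'
#' OLS slope of the gene statistic on a continuous per-gene property
#' (for example, tissue expression), one-sided greater.
#'
#' @param gene_stats Numeric vector of per-gene statistics.
#' @param property_values Numeric vector, same length.
#' @return List with `beta`, `se`, `t`, `pvalue`, `df`.
#' @export
enrich_property <- function(gene_stats, property_values) {
  stopifnot(length(gene_stats) == length(property_values))
  ols_one_sided(gene_stats, property_values, "property")
}

#' Run the GWAS gene stage end to end
#'
#' Maps SNPs to genes, aggregates per-gene p-values with Fisher's
#' method, applies the Bonferroni gene threshold, and (optionally) runs
#' competitive enrichment over supplied gene sets using the per-gene
#' `-log10 p` statistic.
#'
#' @param snps Data.frame of SNP records.
#' @param genes Data.frame of gene models.
#' @param gene_sets Optional named list of gene-id vectors.
#' @param cfg Config list from [default_config()].
#' @return List with `snp_catalogue`, `gene_level` (gene_id, n_snps,
#'   stat, df, pvalue, significant), `bonferroni`, and `enrichment`
#'   (NULL if no sets given).
#' @export
run_gwas_genes <- function(snps, genes, gene_sets = NULL, cfg = default_config()) {
  catalogue <- filter_snps(snps, cfg$snp_p)
  pairs <- map_snps_to_genes(snps, genes, cfg$window_bp)
  pmap <- setNames(snps$pvalue, snps$snp_id)
  by_gene <- split(pairs$snp_id, pairs$gene_id)
  gene_level <- do.call(rbind, lapply(names(by_gene), function(g) {
    res <- gene_level_pvalue(pmap[by_gene[[g]]])
    data.frame(gene_id = g, n_snps = length(by_gene[[g]]),
               stat = res$stat, df = res$df, pvalue = res$pvalue)
  }))
  if (is.null(gene_level)) {
    gene_level <- data.frame(gene_id = character(0), n_snps = integer(0),
                             stat = numeric(0), df = numeric(0), pvalue = numeric(0))
  }
  bonf <- if (nrow(gene_level) > 0) {
    bonferroni_threshold(nrow(gene_level), cfg$gene_alpha)
  } else NA_real_
  gene_level$significant <- !is.na(bonf) & gene_level$pvalue < bonf
  gene_level <- gene_level[order(gene_level$pvalue, gene_level$gene_id), ]
  rownames(gene_level) <- NULL

  enr <- NULL
  if (!is.null(gene_sets) && nrow(gene_level) >= 4) {
    statv <- -log10(gene_level$pvalue)
    enr <- do.call(rbind, lapply(names(gene_sets), function(nm) {
      memb <- gene_level$gene_id %in% gene_sets[[nm]]
      if (sum(memb) < 2 || sum(!memb) < 2) return(NULL)
      r <- enrich_competitive(statv, memb)
      data.frame(set_name = nm, n_members_used = sum(memb),
                 beta = r$beta, se = r$se, t = r$t, pvalue = r$pvalue)
    }))
    if (!is.null(enr)) {
      enr$p_adj <- bh_adjust(enr$pvalue)
      rownames(enr) <- NULL
    }
  }
  list(snp_catalogue = catalogue, gene_level = gene_level,
       bonferroni = bonf, enrichment = enr)
}
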