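# Stage 2: summary-statistic TWAS gene z-scores, direction-consistency
# selection across brain regions, Fisher sum-of-logs meta-analysis and
# Benjamini-Hochberg adjustment.

#' Summary-statistic TWAS gene association z-score
#'
#' Standard summary-PrediXcan association: with eQTL weights `w_l`,
#' reference-panel allele-dosage standard deviations `sigma_l`, SNP
#' z-scores `z_l` and SNP covariance `Sigma`,
#' `Z_g = sum_l w_l sigma_l z_l / sigma_g` where
#' `sigma_g^2 = w' Sigma w`.
#'
#' @param model List with `weights` and `snp_sd`, both named numeric
#'   vectors keyed by SNP id (see also [read_gene_stats()] for the
#'   precomputed route).
#' @param snp_z Named numeric vector of GWAS SNP z-scores covering all
#'   model SNPs with nonzero weight.
#' @param snp_cov Covariance matrix over the model SNPs (dimnames
#'   optional; SNP order taken from `model$weights` when absent).
#' @return The gene z-score (numeric scalar).
#' @export
spredixcan_z <- function(model, snp_z, snp_cov) {
  w <- model$weights
  ids <- names(w)
  if (is.null(ids)) stopf("model weights must be a named vector")
  sds <- model$snp_sd[ids]
  if (any(is.na(sds))) stopf("snp_sd missing for some model SNPs")
  nz <- ids[w[ids] != 0]
  if (any(!nz %in% names(snp_z))) {
    stopf("snp_z missing for model SNP(s): %s",
          paste(setdiff(nz, names(snp_z)), collapse = ", "))
  }
  S <- as.matrix(snp_cov)
  if (!is.null(dimnames(S)[[1]])) S <- S[ids, ids, drop = FALSE]
  if (nrow(S) != length(ids)) stopf("snp_cov non-conformable with model SNPs")
  sigma_g2 <- drop(t(w) %*% S %*% w)
  if (sigma_g2 <= 0) stopf("degenerate model: predicted expression variance is 0")
  z <- snp_z[ids]; z[is.na(z)] <- 0
  sum(w * sds * z) / sqrt(sigma_g2)
}

#' Two-sided normal-tail p-value for a z-score
#'
#' `p = 2 * (1 - Phi(|z|))`, clipped into `(eps, 1]` so downstream log
#' transforms are safe.
#'
#' @param z Numeric vector of z-scores.
#' @return Numeric vector of p-values.
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Select genes with direction-consistent regional significance
#'
#' A gene is selected "up" when it has z > 0 with p < `alpha` in at
#' least `min_regions` regions and fewer than `min_regions` significant
#' negative regions ("down" symmetric). Genes significant in both
#' directions in >= `min_regions` regions each are flagged `conflict`
#' and not selected.
#'
#' @param stats Data.frame with one row per (gene, region): columns
#'   `gene_id`, `region`, `zscore`, `pvalue`.
#' @param min_regions Minimum same-direction significant regions,
#'   default 3.
#' @param alpha Per-region significance level, default 0.05.
#' @return Data.frame with columns `gene_id`, `n_regions`, `n_sig_pos`,
#'   `n_sig_neg`, `direction`, `consistent_selected`.
#' @export
select_consistent_genes <- function(stats, min_regions = 3L, alpha = 0.05) {
  stopifnot(min_regions >= 1)
  if (anyDuplicated(paste(stats$gene_id, stats$region, sep = "\r"))) {
    stopf("duplicate (gene, region) rows in TWAS statistics")
  }
  sig_pos <- stats$pvalue < alpha & stats$zscore > 0
  sig_neg <- stats$pvalue < alpha & stats$zscore < 0
  df <- data.frame(gene_id = stats$gene_id, n_regions = 1L,
                   n_sig_pos = as.integer(sig_pos),
                   n_sig_neg = as.integer(sig_neg))
  agg <- stats::aggregate(cbind(n_regions, n_sig_pos, n_sig_neg) ~ gene_id,
                          data = df, FUN = sum)
  up <- agg$n_sig_pos >= min_regions
  dn <- agg$n_sig_neg >= min_regions
  agg$direction <- ifelse(up & dn, "conflict",
                          ifelse(up, "up", ifelse(dn, "down", "none")))
  if (any(agg$direction == "conflict")) {
    pkg_log("warn", sprintf(
      "select_consistent_genes: %d gene(s) significant in both directions; excluded as 'conflict'",
      sum(agg$direction == "conflict")))
  }
  agg$consistent_selected <- agg$direction %in% c("up", "down")
  agg <- agg[order(agg$gene_id), ]
  rownames(agg) <- NULL
  agg
}

#' Fisher's sum-of-logs meta-analysis
#'
#' Combines k independent p-values: `stat = -2 sum(log p)` is chi-square
#' with 2k degrees of freedom.
#'
#' @param pvalues Numeric vector in (0, 1], non-empty.
#' @return List with `stat`, `df`, `p_meta`.
#' @export
fisher_meta <- function(pvalues) {
  if (length(pvalues) == 0) stopf("fisher_meta: empty p-value list")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("fisher_meta: p-values must lie in (0, 1]")
  }
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(stat = stat, df = df,
       p_meta = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values `adj_(i) = min_{j >= i} p_(j) * m / j` (on the
#' ascending-sorted scale), capped at 1 and returned in input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  o <- order(pvalues)
  ps <- pvalues[o]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Cross-region TWAS meta-analysis
#'
#' Applies [select_consistent_genes()], then Fisher meta-analysis per
#' gene over all regions with available statistics, BH adjustment within
#' the consistency-selected gene family (configurable to all genes), and
#' flags the final meta-selected genes.
#'
#' @param stats Data.frame of per-(gene, region) TWAS statistics.
#' @param cfg Config list (uses `min_regions`, `consistency_alpha`,
#'   `meta_alpha`).
#' @param bh_family `"selected"` (default; BH within the
#'   consistency-selected family) or `"all"`.
#' @return Data.frame with one row per gene: selection counts and
#'   direction, `fisher_stat`, `df`, `p_meta`, `p_adj` (NA outside the
#'   BH family), `consistent_selected`, `meta_selected`.
#' @export
run_twas_meta <- function(stats, cfg = default_config(),
                          bh_family = c("selected", "all")) {
  bh_family <- match.arg(bh_family)
  sel <- select_consistent_genes(stats, cfg$min_regions, cfg$consistency_alpha)
  metas <- lapply(split(stats$pvalue, stats$gene_id), fisher_meta)
  ord <- match(sel$gene_id, names(metas))
  sel$fisher_stat <- vapply(metas[ord], `[[`, numeric(1), "stat")
  sel$df <- vapply(metas[ord], `[[`, integer(1), "df")
  sel$p_meta <- vapply(metas[ord], `[[`, numeric(1), "p_meta")
  sel$p_adj <- NA_real_
  fam <- if (bh_family == "selected") which(sel$consistent_selected) else seq_len(nrow(sel))
  if (length(fam) > 0) sel$p_adj[fam] <- bh_adjust(sel$p_meta[fam])
  sel$meta_selected <- sel$consistent_selected & !is.na(sel$p_adj) &
    sel$p_adj < cfg$meta_alpha
  n_up <- sum(sel$meta_selected & sel$direction == "up")
  n_dn <- sum(sel$meta_selected & sel$direction == "down")
  pkg_log("info", sprintf(
    "twas-meta: %d consistency-selected, %d meta-selected (%d up, %d down)",
    sum(sel$consistent_selected), sum(sel$meta_selected), n_up, n_dn))
  sel
}
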