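# Stage 4: sex-stratified differential expression on RNA-seq counts.
# Low-expression filtering on CPM, TMM library normalization
# (trimmed mean of M-values, re-implemented), a covariate-adjusted
# log2-CPM linear model per gene, soft/strict DEG classification, and
# TWAS-vs-transcriptome direction concordance.

cpm_matrix <- function(counts, lib = colSums(counts)) {
  if (any(lib == 0)) {
    stopf("zero-total library for sample '%s'", colnames(counts)[which(lib == 0)[1]])
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Keeps a gene when its CPM (on raw library sizes) exceeds `min_cpm`
#' in at least `min_samples` samples.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param min_cpm CPM threshold, default 1.
#' @param min_samples Minimum number of samples above threshold;
#'   defaults to the smallest diagnosis-arm size when `meta` is given,
#'   else 2.
#' @param meta Optional sample metadata (used only for the default
#'   `min_samples`).
#' @return The row-subset count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = NULL,
                                  meta = NULL) {
  if (is.null(min_samples)) {
    min_samples <- if (!is.null(meta)) min(table(meta$diagnosis)) else 2L
  }
  cpm <- cpm_matrix(counts)
  keep <- rowSums(cpm > min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

# Single-pair TMM factor: trimmed, precision-weighted mean of M-values
# of `obs` against `ref` (the published TMM recipe: 30% two-sided trim
# on M, 5% on A, inverse asymptotic-variance weights).
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0) {
    pkg_log("warn", "tmm_factors: no common positive genes with reference; factor 1")
    return(1)
  }
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference is the sample whose
#' upper-quartile CPM is closest to the mean upper-quartile; per sample
#' the factor is two to the precision-weighted, doubly trimmed mean of
#' M-values against the reference; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples (>= 2
#'   samples, all library totals positive).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stopf("tmm_factors: need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stopf("zero-total library for sample '%s'", colnames(counts)[which(lib == 0)[1]])
  }
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

check_design <- function(X, covariate_names) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    culprit <- aliased[1]
    for (cv in covariate_names) if (any(grepl(cv, aliased, fixed = TRUE))) culprit <- cv
    stopf("singular design: covariate '%s' is confounded", culprit)
  }
  qrX
}

#' Per-gene differential expression test
#'
#' Fits, for every gene, a linear model of log2-CPM (TMM-adjusted
#' library sizes, prior count 0.5) on diagnosis plus covariates. The
#' diagnosis coefficient is the log2 fold change (case vs control); its
#' two-sided t p-value on the residual degrees of freedom is reported,
#' with BH adjustment across genes.
#'
#' @param counts Integer matrix, genes x samples.
#' @param meta Sample metadata with `sample_id`, `diagnosis` (levels
#'   control/case order taken as sorted unless a `control` level
#'   exists).
#' @param covariate_names Character vector of numeric metadata columns
#'   to adjust for.
#' @param prior_count Pseudo-count for the log transform, default 0.5.
#' @return Data.frame with `gene_id`, `logFC`, `t`, `pvalue`, `p_adj`.
#' @export
dge_test <- function(counts, meta, covariate_names = character(0),
                     prior_count = 0.5) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) stopf("metadata missing for some count columns")
  dlev <- unique(meta$diagnosis)
  ref_level <- if ("control" %in% dlev) "control" else sort(dlev)[1]
  diagnosis <- stats::relevel(factor(meta$diagnosis), ref = ref_level)
  if (nlevels(diagnosis) != 2) stopf("diagnosis must have exactly 2 levels")
  if (min(table(diagnosis)) < 2) stopf("need >= 2 samples per diagnosis arm")
  lib <- colSums(counts)
  eff <- lib * tmm_factors(counts)
  logcpm <- log2(sweep(counts + prior_count, 2, eff + 1, "/") * 1e6)
  dat <- data.frame(diagnosis = diagnosis)
  for (cv in covariate_names) {
    if (!cv %in% names(meta)) stopf("covariate '%s' absent from metadata", cv)
    dat[[cv]] <- meta[[cv]]
  }
  X <- stats::model.matrix(stats::reformulate(c("diagnosis", covariate_names)),
                           data = dat)
  qrX <- check_design(X, covariate_names)
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 1) stopf("no residual degrees of freedom (n=%d, p=%d)", n, p)
  fit <- lm.fit(X, t(logcpm))
  coefs <- fit$coefficients
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  jdx <- which(colnames(X) == paste0("diagnosis", levels(diagnosis)[2]))
  se <- sqrt(sigma2 * xtx_inv[jdx, jdx])
  logfc <- coefs[jdx, ]
  tval <- ifelse(se == 0, 0, logfc / se)
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  data.frame(gene_id = rownames(counts), logFC = unname(logfc),
             t = unname(tval), pvalue = unname(pval),
             p_adj = bh_adjust(pval), row.names = NULL)
}

#' Classify differentially expressed genes
#'
#' Soft: `|logFC| > soft[1]` and raw `pvalue < soft[2]`. Strict:
#' `|logFC| > strict[1]` and adjusted `p_adj < strict[2]`. Boundary
#' values are excluded (strict inequalities).
#'
#' @param results Data.frame from [dge_test()].
#' @param soft,strict Length-2 vectors `(lfc, p)`.
#' @return `results` with logical columns `soft_deg`, `strict_deg`.
#' @export
classify_degs <- function(results, soft = c(0.5, 0.05), strict = c(1, 0.05)) {
  stopifnot(all(soft > 0), all(strict > 0))
  results$soft_deg <- abs(results$logFC) > soft[1] & results$pvalue < soft[2]
  results$strict_deg <- abs(results$logFC) > strict[1] & results$p_adj < strict[2]
  results
}

#' Sex-stratified differential expression over all strata
#'
#' Splits samples by (dataset, sex, region), runs the filter +
#' normalization + test chain per stratum (strata with fewer than two
#' samples in either diagnosis arm are skipped with a warning), and
#' classifies DEGs at the configured soft/strict thresholds.
#'
#' @param counts Integer matrix, genes x samples.
#' @param meta Sample metadata table.
#' @param covariate_names Covariates to adjust for.
#' @param cfg Config list.
#' @return List with `strata` (named list of DEG tables; names
#'   `dataset.sex.region`) and `summary` (DEG counts per stratum).
#' @export
run_stratified <- function(counts, meta, covariate_names = character(0),
                           cfg = default_config()) {
  key <- interaction(meta$dataset, meta$sex, meta$region, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- meta[key == k, , drop = FALSE]
    arms <- table(sub$diagnosis)
    if (length(arms) < 2 || min(arms) < 2) {
      pkg_log("warn", sprintf("stratum %s skipped: <2 samples per arm", k))
      next
    }
    cs <- counts[, sub$sample_id, drop = FALSE]
    cs <- filter_low_expression(cs, cfg$min_cpm, meta = sub)
    if (nrow(cs) == 0) {
      pkg_log("warn", sprintf("stratum %s skipped: no gene passes expression filter", k))
      next
    }
    res <- dge_test(cs, sub, covariate_names)
    res <- classify_degs(res,
                         soft = c(cfg$deg_soft_lfc, cfg$deg_soft_p),
                         strict = c(cfg$deg_strict_lfc, cfg$deg_strict_p))
    out[[k]] <- res
  }
  summary <- do.call(rbind, lapply(names(out), function(k) {
    data.frame(stratum = k, n_genes_tested = nrow(out[[k]]),
               n_soft = sum(out[[k]]$soft_deg),
               n_strict = sum(out[[k]]$strict_deg))
  }))
  list(strata = out, summary = summary)
}

#' TWAS-vs-transcriptome direction concordance
#'
#' For genes that are both TWAS meta-selected and soft DEGs in a
#' stratum, compares the TWAS direction with the sign of the observed
#' logFC.
#'
#' @param twas Data.frame from [run_twas_meta()].
#' @param dge_strata Named list of classified DEG tables (as returned
#'   in `run_stratified()$strata`).
#' @return Long data.frame (`gene_id`, `stratum`, `twas_dir`,
#'   `dge_dir`, `concordant`) with a `by_sex` attribute giving the
#'   concordance fraction per sex (sex parsed from the stratum key).
#' @export
direction_concordance <- function(twas, dge_strata) {
  tw <- twas[twas$meta_selected & twas$direction %in% c("up", "down"), ]
  rows <- lapply(names(dge_strata), function(k) {
    d <- dge_strata[[k]]
    d <- d[d$soft_deg & d$gene_id %in% tw$gene_id, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    twd <- tw$direction[match(d$gene_id, tw$gene_id)]
    dged <- ifelse(d$logFC > 0, "up", "down")
    data.frame(gene_id = d$gene_id, stratum = k, twas_dir = twd,
               dge_dir = dged, concordant = twd == dged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), stratum = character(0),
                      twas_dir = character(0), dge_dir = character(0),
                      concordant = logical(0))
  }
  sex <- vapply(strsplit(out$stratum, ".", fixed = TRUE),
                function(p) if (length(p) >= 2) p[2] else NA_character_,
                character(1))
  by_sex <- if (nrow(out) > 0) {
    tapply(out$concordant, sex, mean)
  } else NULL
  attr(out, "by_sex") <- by_sex
  out
}
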