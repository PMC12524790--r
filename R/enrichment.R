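# Stage 3: pathway-level inference. Two engines:
#  - uncertainty-weighted regression enrichment for TWAS signatures
#    (GIGSEA-style: cross-validation r2 enters as WLS weights), and
#  - weighted Kolmogorov-Smirnov rank enrichment (GSEA) for logFC
#    signatures.
# Both use gene-label permutation nulls with a plus-one empirical
# two-sided p, a normalized score, and BH adjustment across sets.

wls_beta1 <- function(y, memb, w) {
  # weighted least squares of y on intercept + membership indicator;
  # closed form for a single binary regressor
  sw <- sum(w)
  mx <- sum(w * memb) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (memb - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum(w * (memb - mx) * (y - my)) / sxx
}

#' Uncertainty-weighted regression enrichment
#'
#' Weighted least squares of the gene signature on a set-membership
#' indicator; prediction uncertainty (e.g. TWAS cross-validation r2)
#' enters as observation weights. The null distribution comes from
#' gene-label permutations of the membership vector (weights stay
#' attached to genes); with `exact = TRUE` and a feasible count, all
#' distinct memberships are enumerated instead.
#'
#' @param signature Named numeric vector, gene -> score (e.g. TWAS z).
#' @param gene_set Character vector of member gene ids.
#' @param weights Optional named numeric vector in (0, 1]; genes missing
#'   from it get weight 1.
#' @param n_perm Number of permutations, default 1000 (warning below
#'   100).
#' @param seed Integer seed for the permutation null.
#' @param exact Enumerate all memberships (only when `choose(N, m)` <=
#'   `exact_limit`).
#' @param exact_limit Cap on exhaustive enumeration size, default 5000.
#' @return List of class `EnrichmentResult`: `set_name`, `n_members_used`,
#'   `effect` (beta1), `nes`, `pvalue`, `direction`, plus `n_perm`.
#' @export
enrich_weighted_regression <- function(signature, gene_set, weights = NULL,
                                       n_perm = 1000L, seed = 1L,
                                       exact = FALSE, exact_limit = 5000) {
  genes <- names(signature)
  if (is.null(genes)) stopf("signature must be a named vector")
  memb <- as.numeric(genes %in% gene_set)
  if (sum(memb) < 2 || sum(memb == 0) < 2) {
    stopf("need >= 2 members and >= 2 non-members present in the signature")
  }
  if (stats::var(memb) == 0) stopf("membership indicator is constant")
  w <- rep(1, length(genes))
  if (!is.null(weights)) {
    hit <- genes %in% names(weights)
    w[hit] <- weights[genes[hit]]
  }
  if (n_perm < 100) pkg_log("warn", "enrich_weighted_regression: n_perm < 100")
  beta <- wls_beta1(signature, memb, w)
  N <- length(genes); m <- sum(memb)
  if (exact && choose(N, m) <= exact_limit) {
    combos <- utils::combn(N, m)
    null_beta <- apply(combos, 2, function(idx) {
      mb <- numeric(N); mb[idx] <- 1
      wls_beta1(signature, mb, w)
    })
  } else {
    set.seed(seed)
    null_beta <- vapply(seq_len(n_perm), function(i) {
      wls_beta1(signature, sample(memb), w)
    }, numeric(1))
  }
  np <- length(null_beta)
  pvalue <- (sum(abs(null_beta) >= abs(beta)) + 1) / (np + 1)
  nsd <- stats::sd(null_beta)
  nes <- if (is.na(nsd) || nsd == 0) 0 else (beta - mean(null_beta)) / nsd
  structure(list(set_name = NA_character_, n_members_used = as.integer(m),
                 effect = beta, nes = nes, pvalue = pvalue,
                 direction = if (beta > 0) "up" else "down", n_perm = np),
            class = "EnrichmentResult")
}

gsea_es <- function(scores_sorted, is_hit, exponent = 1) {
  # running-sum enrichment score over a descending-sorted signature
  N <- length(scores_sorted)
  nh <- sum(is_hit)
  if (nh == 0) stopf("gene set does not intersect the ranking")
  if (nh == N) return(1)   # all hits: running sum climbs to exactly 1
  wts <- abs(scores_sorted)^exponent
  inc <- ifelse(is_hit, wts / sum(wts[is_hit]), 0)
  dec <- ifelse(is_hit, 0, 1 / (N - nh))
  run <- cumsum(inc - dec)
  i <- which.max(abs(run))
  run[i]
}

#' Rank-based (GSEA) enrichment with a weighted running sum
#'
#' Genes are sorted by descending score; each member "hit" advances the
#' running sum by its |score|^exponent share, each miss retreats it by
#' `1/(N - N_set)`. The enrichment score ES is the extremum of the
#' running sum; the null comes from gene-label permutations; NES is
#' ES divided by the mean |null ES| of matching sign.
#'
#' @param ranking Named numeric vector, gene -> score (not all equal).
#' @param gene_set Character vector of member ids (>= 1 in ranking).
#' @param exponent Weighting exponent, default 1.
#' @param n_perm Permutations for the null, default 1000.
#' @param seed Integer seed.
#' @return `EnrichmentResult` list with `effect` = ES, `nes`, `pvalue`,
#'   `direction`.
#' @export
enrich_gsea <- function(ranking, gene_set, exponent = 1, n_perm = 1000L,
                        seed = 1L) {
  genes <- names(ranking)
  if (is.null(genes)) stopf("ranking must be a named vector")
  if (length(unique(ranking)) == 1) stopf("ranking values are all equal")
  hits <- genes %in% gene_set
  if (!any(hits)) stopf("gene set does not intersect the ranking")
  o <- order(ranking, decreasing = TRUE)
  s <- ranking[o]; h <- hits[o]
  es <- gsea_es(s, h, exponent)
  set.seed(seed)
  nh <- sum(h); N <- length(s)
  null_es <- vapply(seq_len(n_perm), function(i) {
    hp <- logical(N); hp[sample.int(N, nh)] <- TRUE
    gsea_es(s, hp, exponent)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) == 0 || mean(abs(same)) == 0) 0 else es / mean(abs(same))
  pvalue <- (sum(abs(null_es) >= abs(es)) + 1) / (n_perm + 1)
  structure(list(set_name = NA_character_, n_members_used = as.integer(nh),
                 effect = es, nes = nes, pvalue = pvalue,
                 direction = if (es > 0) "up" else "down", n_perm = n_perm),
            class = "EnrichmentResult")
}

#' Enrich a whole gene-set catalogue
#'
#' Applies the chosen engine to every set that passes the size filter
#' (membership counted after intersection with the signature), then BH
#' adjustment across retained sets.
#'
#' @param signature Named numeric vector gene -> score.
#' @param sets Named list of member-id vectors (e.g. from [read_gmt()]).
#' @param mode `"regression"` or `"gsea"`.
#' @param weights Optional named weights (regression mode).
#' @param cfg Config list (uses `min_set_size`, `max_set_size`,
#'   `n_perm`, `seed`).
#' @return Data.frame: one row per retained set with `set_name`,
#'   `n_members_used`, `effect`, `nes`, `pvalue`, `p_adj`, `direction`.
#' @export
enrich_catalogue <- function(signature, sets, mode = c("regression", "gsea"),
                             weights = NULL, cfg = default_config()) {
  mode <- match.arg(mode)
  genes <- names(signature)
  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= cfg$min_set_size & sizes <= cfg$max_set_size
  if (!any(keep)) {
    pkg_log("warn", "enrich_catalogue: no gene set survives the size filter")
    return(data.frame(set_name = character(0), n_members_used = integer(0),
                      effect = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), p_adj = numeric(0),
                      direction = character(0)))
  }
  rows <- lapply(names(sets)[keep], function(nm) {
    seed_i <- derive_seed(cfg$seed, paste0("enrich:", nm))
    r <- if (mode == "regression") {
      enrich_weighted_regression(signature, sets[[nm]], weights,
                                 n_perm = cfg$n_perm, seed = seed_i)
    } else {
      enrich_gsea(signature, sets[[nm]], n_perm = cfg$n_perm, seed = seed_i)
    }
    data.frame(set_name = nm, n_members_used = r$n_members_used,
               effect = r$effect, nes = r$nes, pvalue = r$pvalue,
               direction = r$direction)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$pvalue)
  out <- out[, c("set_name", "n_members_used", "effect", "nes",
                 "pvalue", "p_adj", "direction")]
  out[order(out$pvalue, out$set_name), ]
}
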