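# Stage 5: master-regulator inference. Transcription-factor activity is
# scored from regulons against a gene signature (signed weighted-mean
# statistic with a gene-permutation null); the signaling network is
# pruned to the expressed tissue; candidate upstream regulators
# (receptors, ligands, kinases, phosphatases) are scored by whether the
# sign products along signed shortest paths to TFs explain the observed
# TF states under an "active" or "inactive" hypothesis.

#' Transcription-factor activity from regulons
#'
#' For each TF, `score = sum_j mode_j * likelihood_j * w_j * x_j /
#' sqrt(sum_j (likelihood_j * w_j)^2)` over regulon targets present in
#' the signature `x`. The null permutes signature values over genes;
#' NES is the null-standardized score and the two-sided empirical
#' p-value uses the plus-one correction. A TF is `active` when p <
#' `tf_alpha` and NES > 0 ("activates up-regulated genes, represses
#' down-regulated ones"), `inactive` when p < `tf_alpha` and NES < 0,
#' else `ns`.
#'
#' @param signature Named numeric vector gene -> score (z or logFC).
#' @param regulons Named list of regulon data.frames (`target`, `mode`,
#'   `likelihood`), see [read_regulons()].
#' @param weights Optional named per-gene weights (default 1).
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed.
#' @param tf_alpha Significance level for calling a state, default 0.05.
#' @param min_regulon_size Minimum usable targets, default 5; smaller
#'   regulons are skipped with a warning.
#' @return Data.frame: `tf_id`, `n_targets_used`, `score`, `nes`,
#'   `pvalue`, `state`.
#' @export
tf_activity <- function(signature, regulons, weights = NULL, n_perm = 1000L,
                        seed = 1L, tf_alpha = 0.05, min_regulon_size = 5L) {
  genes <- names(signature)
  if (is.null(genes)) stopf("signature must be a named vector")
  w <- rep(1, length(genes)); names(w) <- genes
  if (!is.null(weights)) {
    hit <- intersect(genes, names(weights))
    w[hit] <- weights[hit]
  }
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(length(genes)))
  rows <- lapply(names(regulons), function(tf) {
    reg <- regulons[[tf]]
    reg <- reg[reg$target %in% genes, , drop = FALSE]
    if (nrow(reg) < min_regulon_size) {
      pkg_log("warn", sprintf("tf_activity: regulon %s has <%d usable targets; skipped",
                              tf, min_regulon_size))
      return(NULL)
    }
    idx <- match(reg$target, genes)
    coef <- reg$mode * reg$likelihood * w[idx]
    denom <- sqrt(sum((reg$likelihood * w[idx])^2))
    score <- sum(coef * signature[idx]) / denom
    null_scores <- vapply(seq_len(n_perm), function(b) {
      xs <- signature[perm_idx[idx, b]]
      sum(coef * xs) / denom
    }, numeric(1))
    mu <- mean(null_scores); sdv <- stats::sd(null_scores)
    nes <- if (is.na(sdv) || sdv == 0) 0 else (score - mu) / sdv
    pvalue <- (sum(abs(null_scores) >= abs(score)) + 1) / (n_perm + 1)
    state <- if (pvalue < tf_alpha && nes > 0) "active"
             else if (pvalue < tf_alpha && nes < 0) "inactive" else "ns"
    data.frame(tf_id = tf, n_targets_used = nrow(reg), score = score,
               nes = nes, pvalue = pvalue, state = state)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_id = character(0), n_targets_used = integer(0),
                      score = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), state = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Prune a network to the expressed tissue
#'
#' Returns the subgraph induced on `expressed` nodes (edges incident to
#' a removed node are dropped). Used with tpm > 1 gene lists for
#' TWAS-derived strata and with filtered count-table gene lists for
#' transcriptomic strata.
#'
#' @param network A `SignedNetwork`.
#' @param expressed Character vector of expressed node ids.
#' @return A pruned `SignedNetwork`.
#' @export
prune_network <- function(network, expressed) {
  keep <- network$edges$source %in% expressed & network$edges$target %in% expressed
  ed <- network$edges[keep, , drop = FALSE]
  ed$sign <- ifelse(ed$sign > 0, "+1", "-1")
  roles <- network$roles[names(network$roles) %in% expressed]
  signed_network(ed, roles)
}

#' Signed shortest paths from a source node
#'
#' Breadth-first layering to depth `max_len` over the directed network,
#' ignoring self-loops. For each reached node the shortest-path length
#' is reported together with the product of edge signs along the
#' shortest paths: `+1`/`-1` when every shortest path agrees, `0` when
#' shortest paths of the same length disagree (ambiguous). Nodes beyond
#' `max_len` (and the source itself) are absent.
#'
#' @param network A `SignedNetwork`.
#' @param source Source node id (must be in the network).
#' @param max_len Maximum path length, default 5.
#' @return Data.frame: `node`, `distance`, `path_sign`.
#' @export
signed_shortest_paths <- function(network, source, max_len = 5L) {
  if (!source %in% network$nodes) stopf("source '%s' not in network", source)
  ed <- network$edges[network$edges$source != network$edges$target, , drop = FALSE]
  adj <- split(seq_len(nrow(ed)), ed$source)
  # per node: distance and the set of achievable shortest-path sign
  # products, encoded as c(pos, neg) flags
  dist <- integer(0); pos <- logical(0); neg <- logical(0)
  frontier <- source
  fpos <- setNames(TRUE, source); fneg <- setNames(FALSE, source)
  d <- 0L
  while (length(frontier) > 0 && d < max_len) {
    d <- d + 1L
    npos <- logical(0); nneg <- logical(0)
    for (u in frontier) {
      eidx <- adj[[u]]
      if (is.null(eidx)) next
      for (i in eidx) {
        v <- ed$target[i]; s <- ed$sign[i]
        if (v == source || v %in% names(dist)) next   # already finalized earlier
        vp <- (s == 1 & fpos[[u]]) | (s == -1 & fneg[[u]])
        vn <- (s == 1 & fneg[[u]]) | (s == -1 & fpos[[u]])
        npos[v] <- isTRUE(npos[v]) | vp
        nneg[v] <- isTRUE(nneg[v]) | vn
      }
    }
    # finalize this layer
    for (v in names(npos)) {
      dist[v] <- d; pos[v] <- npos[[v]]; neg[v] <- nneg[[v]]
    }
    frontier <- names(npos)
    fpos <- npos; fneg <- nneg
  }
  if (length(dist) == 0) {
    return(data.frame(node = character(0), distance = integer(0),
                      path_sign = integer(0)))
  }
  sign_out <- ifelse(pos & neg, 0L, ifelse(pos, 1L, -1L))
  out <- data.frame(node = names(dist), distance = unname(dist),
                    path_sign = unname(sign_out))
  out[order(out$distance, out$node), ]
}

#' Causal agreement score for one regulator hypothesis
#'
#' For each TF reachable with an unambiguous path sign and a non-null
#' observed state, the predicted state is `hypothesis x path_sign`;
#' matches count as correct, mismatches as incorrect. Ambiguous paths
#' (sign 0) and unexplained TFs (observed state 0) are tallied
#' separately. `score = n_correct - n_incorrect`.
#'
#' @param path_signs Named integer vector TF -> path sign in
#'   `{-1, 0, 1}`.
#' @param tf_states Named integer vector TF -> observed state in
#'   `{-1, 0, 1}` (+1 active, -1 inactive).
#' @param hypothesis `+1` (regulator active) or `-1` (inactive).
#' @return List: `score`, `n_correct`, `n_incorrect`, `n_ambiguous`,
#'   `n_unexplained`.
#' @export
score_regulator <- function(path_signs, tf_states, hypothesis) {
  stopifnot(hypothesis %in% c(-1, 1))
  shared <- intersect(names(path_signs), names(tf_states))
  ps <- path_signs[shared]; st <- tf_states[shared]
  amb <- ps == 0
  unexp <- !amb & st == 0
  use <- !amb & !unexp
  pred <- hypothesis * ps[use]
  n_cor <- sum(pred == st[use])
  n_inc <- sum(pred == -st[use])
  list(score = n_cor - n_inc, n_correct = n_cor, n_incorrect = n_inc,
       n_ambiguous = sum(amb), n_unexplained = sum(unexp))
}

#' Identify candidate master regulators
#'
#' Every node whose role is in `candidate_roles` is scored under both
#' the active (+1) and inactive (-1) hypothesis against the observed TF
#' states via [signed_shortest_paths()] and [score_regulator()]; the
#' better hypothesis is kept (an exact tie reports both rows with
#' `tie = TRUE`). Candidates are ranked by score (descending), then
#' `n_correct` (descending), then regulator id. A candidate is
#' `retained` when `score >= min_score` and it has TWAS or DEG support
#' (both, with `require_both`).
#'
#' @param network Pruned `SignedNetwork`.
#' @param tf_states Named vector TF -> state in `{-1, 0, 1}` (e.g.
#'   from [tf_activity()]: active = +1, inactive = -1, ns = 0).
#' @param twas_genes,deg_genes Character sets used for the support
#'   flags.
#' @param candidate_roles Roles eligible as regulators.
#' @param max_len Maximum signed-path length, default 5.
#' @param min_score Minimum net explained TFs, default 2.
#' @param require_both Require both support criteria (default FALSE:
#'   either suffices).
#' @return Data.frame of ranked `MrResult` rows.
#' @export
find_master_regulators <- function(network, tf_states,
                                   twas_genes = character(0),
                                   deg_genes = character(0),
                                   candidate_roles = c("receptor", "ligand",
                                                       "kinase", "phosphatase"),
                                   max_len = 5L, min_score = 2L,
                                   require_both = FALSE) {
  if (length(tf_states) == 0) stopf("tf_states is empty")
  cands <- sort(names(network$roles)[network$roles %in% candidate_roles])
  rows <- lapply(cands, function(cd) {
    sp <- signed_shortest_paths(network, cd, max_len)
    ps <- setNames(sp$path_sign, sp$node)
    ps <- ps[names(ps) %in% names(tf_states)]
    sc_a <- score_regulator(ps, tf_states, +1)
    sc_i <- score_regulator(ps, tf_states, -1)
    pick <- if (sc_a$score > sc_i$score) list(c("active" = 1)) else
            if (sc_i$score > sc_a$score) list(c("inactive" = -1)) else
            list(c("active" = 1), c("inactive" = -1))
    tie <- length(pick) == 2
    do.call(rbind, lapply(pick, function(h) {
      sc <- if (h > 0) sc_a else sc_i
      data.frame(regulator_id = cd, role = unname(network$roles[cd]),
                 hypothesis = names(h), score = sc$score,
                 n_correct = sc$n_correct, n_incorrect = sc$n_incorrect,
                 n_ambiguous = sc$n_ambiguous,
                 n_unexplained = sc$n_unexplained, tie = tie)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(regulator_id = character(0), role = character(0),
                      hypothesis = character(0), score = integer(0),
                      n_correct = integer(0), n_incorrect = integer(0),
                      n_ambiguous = integer(0), n_unexplained = integer(0),
                      tie = logical(0), twas_support = logical(0),
                      dge_support = logical(0), retained = logical(0)))
  }
  out$twas_support <- out$regulator_id %in% twas_genes
  out$dge_support <- out$regulator_id %in% deg_genes
  support <- if (require_both) out$twas_support & out$dge_support
             else out$twas_support | out$dge_support
  out$retained <- out$score >= min_score & support
  out <- out[order(-out$score, -out$n_correct, out$regulator_id), ]
  rownames(out) <- NULL
  out
}

#' Run master-regulator inference across strata
#'
#' Per stratum: prune the network to the stratum's expressed gene set,
#' score TF activity on the stratum signature, then rank candidate
#' regulators. Also builds a regulator x stratum state matrix with a
#' four-level encoding: `active+`/`active-` (active hypothesis,
#' regulator gene itself up/unmeasured vs down in the signature) and
#' `inactive+`/`inactive-`.
#'
#' @param signatures Named list: stratum -> named numeric signature.
#' @param regulons Named regulon list.
#' @param network Full `SignedNetwork`.
#' @param expressed_sets Named list: stratum -> expressed gene ids
#'   (tpm > 1 lists for TWAS strata; filtered count gene lists for
#'   transcriptomic strata).
#' @param twas_genes,deg_genes Support sets for the retention filter.
#' @param cfg Config list.
#' @return List: `per_stratum` (MrResult tables), `tf_activity`
#'   (per-stratum TF tables), `state_matrix` (regulator x stratum
#'   character matrix).
#' @export
run_regulators <- function(signatures, regulons, network, expressed_sets,
                           twas_genes = character(0), deg_genes = character(0),
                           cfg = default_config()) {
  per <- list(); tfs <- list()
  for (st in names(signatures)) {
    expr <- expressed_sets[[st]] %||% names(signatures[[st]])
    pruned <- prune_network(network, expr)
    act <- tf_activity(signatures[[st]], regulons,
                       n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, paste0("tf:", st)),
                       tf_alpha = cfg$tf_alpha,
                       min_regulon_size = cfg$min_regulon_size)
    states <- setNames(ifelse(act$state == "active", 1L,
                              ifelse(act$state == "inactive", -1L, 0L)),
                       act$tf_id)
    if (all(states == 0) || length(states) == 0) {
      pkg_log("warn", sprintf("run_regulators: stratum %s has no significant TF; skipped", st))
      next
    }
    mr <- find_master_regulators(pruned, states, twas_genes, deg_genes,
                                 max_len = cfg$max_path_len,
                                 min_score = cfg$min_score,
                                 require_both = isTRUE(cfg$require_both))
    per[[st]] <- mr; tfs[[st]] <- act
  }
  regs <- sort(unique(unlist(lapply(per, function(m) m$regulator_id))))
  mat <- matrix(NA_character_, nrow = length(regs), ncol = length(per),
                dimnames = list(regs, names(per)))
  for (st in names(per)) {
    m <- per[[st]]
    m <- m[!duplicated(m$regulator_id), ]     # on tie keep the ranked-first row
    sig <- signatures[[st]]
    own <- sig[m$regulator_id]
    updn <- ifelse(!is.na(own) & own < 0, "-", "+")
    mat[m$regulator_id, st] <- paste0(m$hypothesis, updn)
  }
  list(per_stratum = per, tf_activity = tfs, state_matrix = mat)
}
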