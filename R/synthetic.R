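# Synthetic-data generators. Every pipeline input can be generated with
# planted ground truth (signal genes, enriched sets, sex-specific and
# sex-opposite expression changes, active/inactive regulators) so the
# whole chain is testable without protected external datasets. All
# generators are deterministic given their seed.

#' Ground-truth container for synthetic data
#'
#' @param signal_genes_up,signal_genes_down Disjoint gene-id sets.
#' @param enriched_sets Named character vector set_name -> direction.
#' @param planted_de Data.frame (`gene_id`, `sex`, `logfc`).
#' @param active_tfs,inactive_tfs TF id sets.
#' @param planted_mrs Named character vector regulator ->
#'   `"active"`/`"inactive"`.
#' @return List of class `GroundTruth`.
#' @export
ground_truth <- function(signal_genes_up = character(0),
                         signal_genes_down = character(0),
                         enriched_sets = character(0),
                         planted_de = NULL,
                         active_tfs = character(0),
                         inactive_tfs = character(0),
                         planted_mrs = character(0)) {
  if (length(intersect(signal_genes_up, signal_genes_down)) > 0) {
    stopf("up and down signal gene sets must be disjoint")
  }
  structure(list(signal_genes_up = signal_genes_up,
                 signal_genes_down = signal_genes_down,
                 enriched_sets = enriched_sets,
                 planted_de = planted_de,
                 active_tfs = active_tfs, inactive_tfs = inactive_tfs,
                 planted_mrs = planted_mrs),
            class = "GroundTruth")
}

#' @rdname ground_truth
#' @param truth A `GroundTruth`.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, dataframe = "columns", null = "null")
  invisible(path)
}

#' Synthetic gene models on a compact genome
#'
#' Non-overlapping gene bodies laid out along a few chromosomes with
#' fixed intergenic gaps; coordinates 1-based inclusive.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes, default 3.
#' @param gene_bp Gene-body length, default 20000.
#' @param gap_bp Intergenic gap, default 80000 (wide enough that 10 kb
#'   windows never overlap neighbours).
#' @return Gene-model data.frame.
#' @export
simulate_gene_models <- function(n_genes, n_chroms = 3L, gene_bp = 20000L,
                                 gap_bp = 80000L) {
  chrom <- rep_len(paste0("chr", seq_len(n_chroms)), n_genes)
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- 1L + (idx - 1L) * (gene_bp + gap_bp)
  data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
             symbol = sprintf("SYM%05d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + gene_bp - 1L,
             strand = rep_len(c("+", "-"), n_genes))
}

#' Simulate GWAS summary statistics with planted loci
#'
#' Null SNPs get p ~ Uniform(0,1) and positions uniform over the
#' chromosome span covered by the gene models. Each planted locus
#' places its SNPs inside the gene's window with
#' `-log10 p = scale + Exponential(1)`, i.e. `scale` is a
#' significance floor with an exponential tail (see the methods
#' vignette for why the floor form is used).
#'
#' @param genes Gene-model data.frame.
#' @param n_snps Total number of SNPs (>= number planted).
#' @param signal_loci Data.frame (`gene_id`, `n_snps`, `scale`) or NULL.
#' @param window_bp Window for placing signal SNPs, default 10000.
#' @param seed Integer seed.
#' @return Data.frame of SNP records.
#' @export
simulate_gwas <- function(genes, n_snps, signal_loci = NULL,
                          window_bp = 10000L, seed = 1L) {
  set.seed(seed)
  n_signal <- if (is.null(signal_loci)) 0L else sum(signal_loci$n_snps)
  if (n_snps < n_signal) stopf("n_snps (%d) < planted SNPs (%d)", n_snps, n_signal)
  spans <- do.call(rbind, lapply(split(genes, genes$chrom), function(g) {
    data.frame(chrom = g$chrom[1], lo = min(g$start), hi = max(g$end))
  }))
  rows <- list()
  if (n_signal > 0) {
    for (i in seq_len(nrow(signal_loci))) {
      gid <- signal_loci$gene_id[i]
      g <- genes[genes$gene_id == gid, ]
      if (nrow(g) == 0) stopf("signal gene '%s' absent from gene table", gid)
      k <- signal_loci$n_snps[i]
      neglog <- signal_loci$scale[i] + stats::rexp(k, rate = 1)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = g$chrom,
        pos = as.integer(round(stats::runif(k, g$start - window_bp, g$end + window_bp))),
        pvalue = pmax(10^(-pmin(neglog, 290)), .Machine$double.xmin))
    }
  }
  n_null <- n_snps - n_signal
  if (n_null > 0) {
    w <- spans$hi - spans$lo + 1
    ch <- sample(nrow(spans), n_null, replace = TRUE, prob = w / sum(w))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = spans$chrom[ch],
      pos = as.integer(round(stats::runif(n_null, spans$lo[ch], spans$hi[ch]))),
      pvalue = stats::runif(n_null))
  }
  if (length(rows) == 0) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), allele_ref = character(0),
                      allele_alt = character(0), pvalue = numeric(0),
                      effect = numeric(0)))
  }
  snps <- do.call(rbind, rows)
  n <- nrow(snps)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  data.frame(snp_id = sprintf("rs%07d", seq_len(n)), chrom = snps$chrom,
             pos = snps$pos, allele_ref = ref, allele_alt = unname(alt),
             pvalue = snps$pvalue,
             effect = stats::rnorm(n, 0, 0.1), row.names = NULL)
}

#' Simulate per-region TWAS gene statistics with a shared latent effect
#'
#' Signal gene g gets a latent effect `mu_g ~ +/- N(effect_mu,
#' effect_sd^2)` shared across regions (transcription changes point the
#' same way in every brain region); its per-region z is `mu_g + N(0,1)`.
#' Null genes draw z ~ N(0,1) independently per region. p-values are
#' two-sided normal tails; cv-r2 ~ Uniform(r2_range) per (gene, region).
#'
#' @param n_genes Total genes.
#' @param n_regions Number of regions, default 15.
#' @param n_up,n_down Planted up/down signal gene counts.
#' @param effect_mu,effect_sd Latent effect magnitude, defaults 4 and 1.
#' @param r2_range cv-r2 range in (0, 1], default c(0.05, 0.8).
#' @param seed Integer seed.
#' @return List: `stats` (long data.frame gene_id, region, zscore,
#'   pvalue, cv_r2) and `truth` (a [ground_truth()]).
#' @export
simulate_twas_tables <- function(n_genes, n_regions = 15L, n_up = 0L,
                                 n_down = 0L, effect_mu = 4, effect_sd = 1,
                                 r2_range = c(0.05, 0.8), seed = 1L) {
  if (n_up + n_down > n_genes) stopf("n_up + n_down exceeds n_genes")
  if (any(r2_range <= 0) || any(r2_range > 1)) stopf("r2_range must lie in (0, 1]")
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  regions <- sprintf("region%02d", seq_len(n_regions))
  pick <- sample(n_genes, n_up + n_down)
  up <- gene_id[pick[seq_len(n_up)]]
  dn <- gene_id[pick[n_up + seq_len(n_down)]]
  mu <- setNames(numeric(n_genes), gene_id)
  if (n_up > 0) mu[up] <- abs(stats::rnorm(n_up, effect_mu, effect_sd))
  if (n_down > 0) mu[dn] <- -abs(stats::rnorm(n_down, effect_mu, effect_sd))
  z <- matrix(stats::rnorm(n_genes * n_regions), n_genes, n_regions) + mu
  stats_df <- data.frame(
    gene_id = rep(gene_id, times = n_regions),
    region = rep(regions, each = n_genes),
    zscore = as.vector(z),
    cv_r2 = stats::runif(n_genes * n_regions, r2_range[1], r2_range[2]))
  stats_df$pvalue <- z_to_p(stats_df$zscore)
  stats_df <- stats_df[, c("gene_id", "region", "zscore", "pvalue", "cv_r2")]
  list(stats = stats_df,
       truth = ground_truth(signal_genes_up = up, signal_genes_down = dn))
}

#' Build gene sets with planted enrichment from TWAS ground truth
#'
#' One set drawn from the planted up-genes, one from the down-genes
#' (when available), plus `n_null_sets` sets of random universe genes.
#'
#' @param truth `GroundTruth` with signal gene sets.
#' @param universe Character vector of all gene ids.
#' @param set_size Members per set, default 20.
#' @param n_null_sets Number of random sets, default 20.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors; planted sets are named
#'   `SET_UP` / `SET_DOWN`, nulls `NULL_k`.
#' @export
simulate_gene_sets <- function(truth, universe, set_size = 20L,
                               n_null_sets = 20L, seed = 1L) {
  set.seed(seed)
  sets <- list()
  if (length(truth$signal_genes_up) >= 2) {
    sets$SET_UP <- sample(truth$signal_genes_up,
                          min(set_size, length(truth$signal_genes_up)))
  }
  if (length(truth$signal_genes_down) >= 2) {
    sets$SET_DOWN <- sample(truth$signal_genes_down,
                            min(set_size, length(truth$signal_genes_down)))
  }
  for (k in seq_len(n_null_sets)) {
    sets[[sprintf("NULL_%02d", k)]] <- sample(universe, set_size)
  }
  attr(sets, "description") <- setNames(rep("synthetic", length(sets)), names(sets))
  sets
}

#' Simulate RNA-seq counts with planted sex-specific expression changes
#'
#' Counts are negative binomial with library-size-scaled gene means;
#' diagnosis multiplies the mean of a planted gene by `2^logfc` in the
#' matching sex only (so sex-opposite effects are planted by giving the
#' same gene opposite `logfc` in the two sexes). Covariates (age, PMI,
#' pH, RIN) act multiplicatively through small per-gene log-linear
#' coefficients and are mildly shifted in cases, so covariate-unaware
#' analysis is measurably miscalibrated.
#'
#' @param n_genes Number of genes.
#' @param samples_per_arm Samples per (sex, region, diagnosis) cell
#'   (scalar >= 1).
#' @param regions Character vector of region labels.
#' @param sexes Character vector, default male/female.
#' @param planted_de Data.frame (`gene_id`, `sex`, `logfc`) or NULL.
#' @param baseline_logmean_range Range of per-gene log2 relative
#'   abundance, default c(1, 9).
#' @param dispersion NB dispersion (1/size), constant across genes,
#'   default 0.1.
#' @param libsize_range Library-size range, default c(1e6, 2e6).
#' @param covariate_effects Named scale of per-gene covariate
#'   coefficients (log2 units per SD), default 0.1 for each of age,
#'   PMI, pH, RIN.
#' @param dataset Dataset label, default "SIM1".
#' @param seed Integer seed.
#' @return List: `counts` (integer matrix), `meta` (sample metadata),
#'   `truth`.
#' @export
simulate_counts <- function(n_genes, samples_per_arm, regions = "BA9",
                            sexes = c("male", "female"), planted_de = NULL,
                            baseline_logmean_range = c(1, 9),
                            dispersion = 0.1, libsize_range = c(1e6, 2e6),
                            covariate_effects = c(age = 0.1, PMI = 0.1,
                                                  pH = 0.1, RIN = 0.1),
                            dataset = "SIM1", seed = 1L) {
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (length(samples_per_arm) != 1 || samples_per_arm < 1) {
    stopf("samples_per_arm must be a scalar >= 1 (zero samples in an arm is an error)")
  }
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  if (!is.null(planted_de) && !all(planted_de$gene_id %in% gene_id)) {
    stopf("planted DE gene(s) outside the simulated gene range")
  }
  grid <- expand.grid(diagnosis = c("control", "MDD"), sex = sexes,
                      region = regions, stringsAsFactors = FALSE)
  meta <- grid[rep(seq_len(nrow(grid)), each = samples_per_arm), ]
  n <- nrow(meta)
  meta$sample_id <- sprintf("S%04d", seq_len(n))
  meta$dataset <- dataset
  case <- as.numeric(meta$diagnosis == "MDD")
  # covariates, mildly shifted in cases so they genuinely confound
  meta$age <- stats::runif(n, 25, 75) + 4 * case
  meta$PMI <- stats::runif(n, 5, 40) + 3 * case
  meta$pH <- stats::runif(n, 6.2, 7.4) - 0.1 * case
  meta$RIN <- stats::runif(n, 5.5, 9) - 0.3 * case
  meta <- meta[, c("sample_id", "diagnosis", "sex", "region", "dataset",
                   "age", "PMI", "pH", "RIN")]
  base <- stats::runif(n_genes, baseline_logmean_range[1], baseline_logmean_range[2])
  q <- 2^base; q <- q / sum(q)
  lib <- stats::runif(n, libsize_range[1], libsize_range[2])
  # per-gene covariate coefficients (log2 units per covariate SD)
  covs <- names(covariate_effects)
  B <- matrix(stats::rnorm(n_genes * length(covs)), n_genes, length(covs)) *
    rep(covariate_effects, each = n_genes)
  Zc <- scale(as.matrix(meta[, covs, drop = FALSE]))
  log2shift <- B %*% t(Zc)                      # genes x samples
  if (!is.null(planted_de)) {
    for (i in seq_len(nrow(planted_de))) {
      gi <- match(planted_de$gene_id[i], gene_id)
      hit <- meta$sex == planted_de$sex[i] & meta$diagnosis == "MDD"
      log2shift[gi, hit] <- log2shift[gi, hit] + planted_de$logfc[i]
    }
  }
  mu <- outer(q, lib) * 2^log2shift
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n, dimnames = list(gene_id, meta$sample_id))
  storage.mode(counts) <- "integer"
  list(counts = counts, meta = meta,
       truth = ground_truth(planted_de = planted_de))
}

#' Simulate regulons, a layered signed network, tpm table and signature
#'
#' Builds a layered graph candidate -> intermediate(s) -> TF. Each
#' planted master regulator is wired to every TF through its own chain
#' of `max_depth - 1` intermediates; TF ground-truth states are fixed
#' first and the chain's edge signs are chosen so that
#' `hypothesis x path-sign product = TF state` (the planted regulator
#' explains all TFs). Decoy candidates are wired to the TFs with
#' deliberately state-inconsistent signs (half agree, half disagree
#' under either hypothesis, so their best score stays near 0). Each
#' TF's regulon targets come from a background gene pool and the
#' returned signature shifts those targets by `state x mode x
#' signal_shift` over N(0,1) noise. A set of unexpressed decoy nodes
#' (tpm 0.5) is attached to test tissue pruning; all other nodes get
#' tpm > 1.
#'
#' @param n_tfs Number of TFs, default 5.
#' @param targets_per_tf Regulon size, default 20.
#' @param n_candidates Total candidate regulators (planted + decoys),
#'   default 10.
#' @param planted_mrs Named character vector regulator ->
#'   `"active"`/`"inactive"` (possibly empty).
#' @param max_depth Path length from candidate to TF, default 2 (must
#'   be <= the `max_path_len` used at inference).
#' @param n_background_genes Background gene pool size, default 2000.
#' @param signal_shift Shift applied to regulon targets, default 2.
#' @param n_unexpressed Number of tpm-0.5 decoy nodes, default 2.
#' @param seed Integer seed.
#' @return List: `regulons`, `network` (`SignedNetwork`), `tpm`
#'   (data.frame gene_id, tpm), `signature` (named vector over
#'   background genes), `truth`.
#' @export
simulate_regulatory_layer <- function(n_tfs = 5L, targets_per_tf = 20L,
                                      n_candidates = 10L,
                                      planted_mrs = c(MR1 = "active"),
                                      max_depth = 2L,
                                      n_background_genes = 2000L,
                                      signal_shift = 2,
                                      n_unexpressed = 2L, seed = 1L) {
  stopifnot(max_depth >= 1)
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  n_planted <- length(planted_mrs)
  if (n_planted > n_candidates) stopf("more planted MRs than candidates")
  decoys <- if (n_candidates > n_planted) {
    sprintf("CAND%02d", seq_len(n_candidates - n_planted))
  } else character(0)
  roles <- c(setNames(rep_len(c("receptor", "ligand", "kinase", "phosphatase"),
                              n_planted), names(planted_mrs)),
             setNames(rep_len(c("receptor", "ligand", "kinase", "phosphatase"),
                              length(decoys)), decoys),
             setNames(rep("TF", n_tfs), tfs))
  tf_state <- setNames(sample(c(-1L, 1L), n_tfs, replace = TRUE), tfs)
  edges <- list(); inter_count <- 0L
  add_chain <- function(cand, tf, want_product) {
    # chain cand -> I1 -> ... -> I_{max_depth-1} -> tf whose sign
    # product equals want_product
    n_int <- max_depth - 1L
    signs <- sample(c(-1L, 1L), max_depth, replace = TRUE)
    signs[max_depth] <- want_product * prod(signs[-max_depth])
    nodes <- cand
    if (n_int > 0) {
      ints <- sprintf("INT%04d", inter_count + seq_len(n_int))
      inter_count <<- inter_count + n_int
      nodes <- c(nodes, ints)
    }
    nodes <- c(nodes, tf)
    for (j in seq_len(max_depth)) {
      edges[[length(edges) + 1]] <<- data.frame(
        source = nodes[j], sign = ifelse(signs[j] > 0, "+1", "-1"),
        target = nodes[j + 1])
    }
    if (n_int > 0) nodes[2:(n_int + 1)] else character(0)
  }
  intermediates <- character(0)
  for (m in names(planted_mrs)) {
    hyp <- if (planted_mrs[[m]] == "active") 1L else -1L
    for (tf in tfs) {
      intermediates <- c(intermediates, add_chain(m, tf, hyp * tf_state[[tf]]))
    }
  }
  for (d in decoys) {
    # half the TF predictions agree with the state, half disagree,
    # under the +1 hypothesis (mirror-image under -1)
    flip <- rep_len(c(1L, -1L), n_tfs)
    for (j in seq_len(n_tfs)) {
      intermediates <- c(intermediates,
                         add_chain(d, tfs[j], flip[j] * tf_state[[tfs[j]]]))
    }
  }
  roles <- c(roles, setNames(rep("other", length(intermediates)), intermediates))
  # unexpressed decoy candidates attached to a TF; pruned away at tpm > 1
  off <- if (n_unexpressed > 0) sprintf("OFF%02d", seq_len(n_unexpressed)) else character(0)
  for (o in off) {
    edges[[length(edges) + 1]] <- data.frame(source = o, sign = "+1", target = tfs[1])
    roles[o] <- "receptor"
  }
  net <- signed_network(do.call(rbind, edges), roles)
  # regulons over a background gene pool, and the matching signature
  pool <- sprintf("BG%05d", seq_len(n_background_genes))
  signature <- stats::rnorm(n_background_genes)
  names(signature) <- pool
  regulons <- list()
  avail <- sample(pool)
  for (i in seq_along(tfs)) {
    tg <- avail[((i - 1) * targets_per_tf + 1):(i * targets_per_tf)]
    mode <- sample(c(-1L, 1L), targets_per_tf, replace = TRUE)
    regulons[[tfs[i]]] <- data.frame(target = tg, mode = mode,
                                     likelihood = stats::runif(targets_per_tf, 0.5, 1))
    signature[tg] <- signature[tg] + tf_state[[tfs[i]]] * mode * signal_shift
  }
  all_nodes <- net$nodes
  tpm <- data.frame(gene_id = all_nodes,
                    tpm = stats::runif(length(all_nodes), 2, 100))
  tpm$tpm[tpm$gene_id %in% off] <- 0.5
  # sanity: every planted MR must reach at least one TF within max_depth
  for (m in names(planted_mrs)) {
    sp <- signed_shortest_paths(net, m, max_len = max_depth)
    if (!any(sp$node %in% tfs)) stopf("planted MR '%s' has no path to any TF", m)
  }
  truth <- ground_truth(active_tfs = tfs[tf_state > 0],
                        inactive_tfs = tfs[tf_state < 0],
                        planted_mrs = planted_mrs)
  list(regulons = regulons, network = net, tpm = tpm,
       signature = signature, truth = truth)
}
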