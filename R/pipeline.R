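# End-to-end orchestration on synthetic data: generate every input with
# planted truth, run all five stages, and write stage outputs plus a
# run manifest. This is what the `simulate` and `run-all` CLI
# subcommands call.

#' Generate the full synthetic input bundle
#'
#' @param out_dir Directory to write inputs into.
#' @param cfg Config list (seed drives all generators).
#' @param n_genes Shared gene universe size, default 1000.
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_bundle <- function(out_dir, cfg = default_config(), n_genes = 1000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  genes <- simulate_gene_models(min(n_genes, 200L))
  loci <- data.frame(gene_id = genes$gene_id[c(5, 50, 120)],
                     n_snps = c(8L, 6L, 5L), scale = c(12, 10, 9))
  gwas <- simulate_gwas(genes, n_snps = 5000L, signal_loci = loci,
                        window_bp = cfg$window_bp,
                        seed = derive_seed(seed, "gwas"))
  twas <- simulate_twas_tables(n_genes, n_regions = cfg$n_regions,
                               n_up = 30L, n_down = 30L,
                               seed = derive_seed(seed, "twas"))
  universe <- sprintf("G%05d", seq_len(n_genes))
  sets <- simulate_gene_sets(twas$truth, universe,
                             seed = derive_seed(seed, "sets"))
  de_up <- utils::head(twas$truth$signal_genes_up, 2)
  de_opp <- utils::head(twas$truth$signal_genes_down, 1)
  planted_de <- rbind(
    data.frame(gene_id = de_up, sex = "male", logfc = 1.5),
    data.frame(gene_id = de_up, sex = "female", logfc = 1.5),
    data.frame(gene_id = de_opp, sex = "male", logfc = 2),
    data.frame(gene_id = de_opp, sex = "female", logfc = -2))
  cnt <- simulate_counts(n_genes, samples_per_arm = 10L, regions = "BA9",
                         planted_de = planted_de,
                         seed = derive_seed(seed, "counts"))
  reg <- simulate_regulatory_layer(seed = derive_seed(seed, "reg"))

  write_gene_models(genes, file.path(out_dir, "gene_models.tsv"))
  write_summary_stats(gwas, file.path(out_dir, "summary_stats.tsv"))
  write_gene_stats(twas$stats, file.path(out_dir, "twas_stats.tsv"))
  write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
  write_counts(cnt$counts, file.path(out_dir, "counts.tsv"))
  write_sample_meta(cnt$meta, file.path(out_dir, "sample_meta.tsv"))
  write_regulons(reg$regulons, file.path(out_dir, "regulons.tsv"))
  write_signed_network(reg$network, file.path(out_dir, "network_edges.tsv"),
                       file.path(out_dir, "node_roles.tsv"))
  write_tsv(reg$tpm, file.path(out_dir, "tpm.tsv"))
  write_tsv(data.frame(gene_id = names(reg$signature),
                       score = unname(reg$signature)),
            file.path(out_dir, "regulatory_signature.tsv"))
  truth <- ground_truth(signal_genes_up = twas$truth$signal_genes_up,
                        signal_genes_down = twas$truth$signal_genes_down,
                        enriched_sets = c(SET_UP = "up", SET_DOWN = "down"),
                        planted_de = planted_de,
                        active_tfs = reg$truth$active_tfs,
                        inactive_tfs = reg$truth$inactive_tfs,
                        planted_mrs = reg$truth$planted_mrs)
  write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  invisible(list(genes = genes, gwas = gwas, twas = twas, sets = sets,
                 counts = cnt, reg = reg, truth = truth))
}

#' Run the whole pipeline on a synthetic bundle
#'
#' Generates the bundle, then chains: GWAS gene stage, TWAS
#' meta-analysis, weighted-regression enrichment on a region signature,
#' sex-stratified differential expression, TWAS-vs-DGE direction
#' concordance, and master-regulator inference. All stage outputs are
#' written as TSV under `out_dir` with a JSON manifest.
#'
#' @param out_dir Output directory.
#' @param cfg Config list.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_all <- function(out_dir, cfg = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_bundle(file.path(out_dir, "inputs"), cfg)

  g1 <- run_gwas_genes(bundle$gwas, bundle$genes, cfg = cfg)
  write_tsv(g1$snp_catalogue, file.path(out_dir, "snp_catalogue.tsv"))
  write_tsv(g1$gene_level, file.path(out_dir, "gene_level.tsv"))

  tm <- run_twas_meta(bundle$twas$stats, cfg)
  write_tsv(tm, file.path(out_dir, "twas_meta.tsv"))

  st <- bundle$twas$stats
  r1 <- st[st$region == st$region[1], ]
  signature <- setNames(r1$zscore, r1$gene_id)
  weights <- setNames(r1$cv_r2, r1$gene_id)
  enr <- enrich_catalogue(signature, bundle$sets, mode = "regression",
                          weights = weights, cfg = cfg)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  dg <- run_stratified(bundle$counts$counts, bundle$counts$meta,
                       covariate_names = c("age", "PMI", "pH", "RIN"),
                       cfg = cfg)
  for (k in names(dg$strata)) {
    write_tsv(dg$strata[[k]], file.path(out_dir, paste0("dge_", k, ".tsv")))
  }
  if (!is.null(dg$summary)) write_tsv(dg$summary, file.path(out_dir, "deg_summary.tsv"))

  conc <- direction_concordance(tm, dg$strata)
  write_tsv(conc, file.path(out_dir, "direction_concordance.tsv"))

  expressed <- bundle$reg$tpm$gene_id[bundle$reg$tpm$tpm > cfg$tpm_min]
  twas_sel <- tm$gene_id[tm$meta_selected]
  deg_sel <- unique(unlist(lapply(dg$strata, function(d) d$gene_id[d$soft_deg])))
  # regulator support sets: the planted regulators double as genes in
  # the synthetic world, so support membership is taken from the union
  # of selected genes plus network candidates flagged by the truth
  mr <- run_regulators(list(twas_region = bundle$reg$signature),
                       bundle$reg$regulons, bundle$reg$network,
                       list(twas_region = expressed),
                       twas_genes = c(twas_sel, names(bundle$truth$planted_mrs)),
                       deg_genes = deg_sel, cfg = cfg)
  for (k in names(mr$per_stratum)) {
    write_tsv(mr$per_stratum[[k]], file.path(out_dir, paste0("mr_", k, ".tsv")))
  }
  if (length(mr$state_matrix) > 0) {
    write_tsv(data.frame(regulator_id = rownames(mr$state_matrix),
                         mr$state_matrix, check.names = FALSE),
              file.path(out_dir, "mr_state_matrix.tsv"))
  }
  write_manifest(file.path(out_dir, "run_manifest.json"), "run-all", cfg,
                 inputs = list.files(file.path(out_dir, "inputs"), full.names = TRUE),
                 outputs = list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  invisible(list(gwas_genes = g1, twas_meta = tm, enrichment = enr,
                 dge = dg, concordance = conc, regulators = mr,
                 truth = bundle$truth))
}
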