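# Run configuration and run manifests.
#
# Configs are JSON on disk (the offline R stack ships no YAML parser);
# every threshold has a package default taken from the study design this
# pipeline re-implements, and any subset of keys may be overridden.

#' Default run configuration
#'
#' Thresholds and sizes for every pipeline stage. Defaults: genome-wide
#' SNP significance 5e-8; SNP-to-gene window 10 kb; per-region TWAS
#' significance 0.05 with >= 3 same-direction regions; BH meta alpha
#' 0.05; soft DEG |logFC| > 0.5 with p < 0.05 and strict |logFC| > 1
#' with adjusted p < 0.05; tissue pruning at tpm > 1; TF activity alpha
#' 0.05; signed shortest paths up to length 5.
#'
#' @param ... Named overrides for any config entry.
#' @return A list of class `twasmr_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    snp_p = 5e-8,
    window_bp = 10000L,
    gene_alpha = 0.05,
    consistency_alpha = 0.05,
    min_regions = 3L,
    meta_alpha = 0.05,
    n_regions = 15L,
    deg_soft_lfc = 0.5, deg_soft_p = 0.05,
    deg_strict_lfc = 1, deg_strict_p = 0.05,
    min_cpm = 1, tpm_min = 1,
    tf_alpha = 0.05,
    min_regulon_size = 5L,
    max_path_len = 5L,
    min_score = 2L,
    require_both = FALSE,
    min_set_size = 5L, max_set_size = 500L,
    n_perm = 1000L,
    seed = 1L
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "twasmr_config")
}

validate_config <- function(cfg) {
  pos <- c("snp_p", "gene_alpha", "consistency_alpha", "meta_alpha",
           "deg_soft_lfc", "deg_soft_p", "deg_strict_lfc", "deg_strict_p",
           "tpm_min", "tf_alpha")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
    stopf("config: '%s' must be positive", k)
  }
  if (cfg$min_regions < 1) stopf("config: min_regions must be >= 1")
  if (cfg$max_path_len < 1) stopf("config: max_path_len must be >= 1")
  invisible(cfg)
}

#' Read a run configuration from JSON
#'
#' Unspecified keys fall back to [default_config()] values.
#'
#' @param path Path to a JSON object of config overrides.
#' @return A `twasmr_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, as.list(over))
}

#' @rdname read_run_config
#' @param cfg A config list.
#' @export
write_run_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

#' Write a run manifest
#'
#' Records inputs, outputs, config hash, seed and package version so a
#' run can be re-executed and compared.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param cfg Config used.
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, cfg, inputs = character(0),
                           outputs = character(0)) {
  man <- list(stage = stage,
              config = unclass(cfg),
              config_hash = config_hash(cfg),
              seed = cfg$seed,
              inputs = as.list(inputs),
              outputs = as.list(outputs),
              package = "twasmr",
              package_version = as.character(utils::packageVersion("twasmr")),
              r_version = as.character(getRversion()))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
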