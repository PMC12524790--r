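# Readers and writers for every on-disk format used by the pipeline.
# All tables are UTF-8 TSV with a header row; genomic coordinates are
# 1-based inclusive throughout. Missing optional values are encoded "NA"
# and dropped with a logged count rather than failing the whole read.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("%s file '%s' is missing required column(s): %s",
          what, path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# GWAS summary statistics --------------------------------------------------

#' Read GWAS summary statistics
#'
#' Reads a tab-separated table of per-SNP association results (no
#' individual-level data). Rows whose p-value cannot be parsed or lies
#' outside (0, 1] are dropped with a logged count.
#'
#' @param path Path to a TSV with columns `snp_id`, `chrom`, `pos`,
#'   `allele_ref`, `allele_alt`, `pvalue`, `effect`.
#' @return A data.frame of SNP records with typed columns; positions are
#'   1-based.
#' @export
read_summary_stats <- function(path) {
  req <- c("snp_id", "chrom", "pos", "allele_ref", "allele_alt",
           "pvalue", "effect")
  df <- read_tsv_checked(path, req, "summary statistics")
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$pvalue <- suppressWarnings(as.numeric(df$pvalue))
  df$effect <- suppressWarnings(as.numeric(df$effect))
  df$chrom <- as.character(df$chrom)
  bad <- is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1 | is.na(df$pos)
  if (any(bad)) {
    pkg_log("warn", sprintf(
      "read_summary_stats: dropped %d of %d rows with unparseable/invalid p or pos",
      sum(bad), nrow(df)))
  }
  df <- df[!bad, req, drop = FALSE]
  if (anyDuplicated(df$snp_id)) {
    stopf("duplicate snp_id values in %s", path)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_summary_stats
#' @param snps Data.frame of SNP records.
#' @export
write_summary_stats <- function(snps, path) write_tsv(snps, path)

# Gene models ---------------------------------------------------------------

#' Read gene models
#'
#' @param path TSV with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @return Data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  req <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  df <- read_tsv_checked(path, req, "gene model")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$chrom <- as.character(df$chrom)
  if (any(df$start > df$end)) stopf("gene model with start > end in %s", path)
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in %s", path)
  df
}

#' @rdname read_gene_models
#' @param genes Data.frame of gene models.
#' @export
write_gene_models <- function(genes, path) write_tsv(genes, path)

# GMT gene sets --------------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated; field 1 is the
#' set name, field 2 a description, fields 3+ the member gene ids.
#' Duplicate members within a set are deduplicated; empty sets are
#' rejected.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of member ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT line %d has %d field(s); at least 3 required (name, description, members)",
            i, length(fields))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stopf("GMT line %d: set '%s' is empty", i, fields[[1]])
    sets[[fields[[1]]]] <- members
    desc[[fields[[1]]]] <- fields[[2]]
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member-id vectors (optionally with a
#'   `description` attribute).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Signed signaling network ---------------------------------------------------

.sign_vocab <- c("1" = 1, "+1" = 1, "activate" = 1, "activates" = 1,
                 "activation" = 1, "-1" = -1, "−1" = -1,
                 "inhibit" = -1, "inhibits" = -1, "inhibition" = -1)

normalize_sign <- function(tokens) {
  key <- tolower(trimws(as.character(tokens)))
  out <- .sign_vocab[key]
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stopf("unrecognized edge sign token '%s' at row %d (accepted: +1, -1, activate(s), inhibit(s))",
          tokens[bad[1]], bad[1])
  }
  unname(out)
}

#' Construct a signed directed network
#'
#' @param edges Data.frame with columns `source`, `sign` (coerced to
#'   +1/-1), `target`.
#' @param roles Named character vector mapping node id to a role in
#'   `{TF, kinase, phosphatase, receptor, ligand, other}`; nodes absent
#'   from `roles` get role `"other"`.
#' @return An object of class `SignedNetwork`: list with `edges` (the
#'   deduplicated edge table), `roles`, `nodes`, and `ambiguous_pairs`
#'   (source/target pairs present with both signs).
#' @export
signed_network <- function(edges, roles = character(0)) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  edges$sign <- normalize_sign(edges$sign)
  edges <- edges[, c("source", "sign", "target")]
  edges <- unique(edges)                      # collapse identical duplicates
  key <- paste(edges$source, edges$target, sep = "\r")
  amb <- unique(key[duplicated(key)])         # same pair, both signs
  if (length(amb) > 0) {
    pkg_log("warn", sprintf(
      "signed_network: %d source->target pair(s) carry contradictory signs; both edges kept",
      length(amb)))
  }
  nodes <- sort(unique(c(edges$source, edges$target, names(roles))))
  role <- setNames(rep("other", length(nodes)), nodes)
  if (length(roles) > 0) role[names(roles)] <- unname(roles)
  structure(list(edges = edges[order(edges$source, edges$target, edges$sign), ],
                 roles = role, nodes = nodes,
                 ambiguous_pairs = do.call(rbind, lapply(strsplit(amb, "\r", fixed = TRUE),
                   function(p) data.frame(source = p[1], target = p[2])))),
            class = "SignedNetwork")
}

#' @export
print.SignedNetwork <- function(x, ...) {
  cat(sprintf("SignedNetwork: %d nodes, %d signed edges (%d activating, %d inhibiting)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

#' Read a signed network from SIF-like TSV files
#'
#' @param edge_path TSV with columns `source`, `sign`, `target`; sign
#'   tokens in `{+1, -1, activate(s), inhibit(s)}` (case-insensitive).
#' @param node_role_path Optional TSV with columns `node`, `role`.
#' @return A [signed_network()] object.
#' @export
read_signed_network <- function(edge_path, node_role_path = NULL) {
  edges <- read_tsv_checked(edge_path, c("source", "sign", "target"), "network edge")
  roles <- character(0)
  if (!is.null(node_role_path)) {
    rdf <- read_tsv_checked(node_role_path, c("node", "role"), "node role")
    ok <- c("TF", "kinase", "phosphatase", "receptor", "ligand", "other")
    bad <- setdiff(unique(rdf$role), ok)
    if (length(bad) > 0) stopf("unknown node role(s): %s", paste(bad, collapse = ", "))
    roles <- setNames(rdf$role, rdf$node)
  }
  signed_network(edges, roles)
}

#' @rdname read_signed_network
#' @param network A `SignedNetwork`.
#' @param role_path Where to write the node-role table.
#' @export
write_signed_network <- function(network, edge_path, role_path = NULL) {
  ed <- network$edges
  ed$sign <- ifelse(ed$sign > 0, "+1", "-1")
  write_tsv(ed[, c("source", "sign", "target")], edge_path)
  if (!is.null(role_path)) {
    write_tsv(data.frame(node = names(network$roles), role = unname(network$roles)),
              role_path)
  }
  invisible(edge_path)
}

# Regulons -------------------------------------------------------------------

#' Read transcription-factor regulons
#'
#' @param path TSV with columns `tf`, `target`, `mode` (sign tokens as in
#'   [read_signed_network()]) and `likelihood` in (0, 1].
#' @return Named list (by TF) of data.frames with columns `target`,
#'   `mode`, `likelihood`; duplicate targets within a TF are an error.
#' @export
read_regulons <- function(path) {
  df <- read_tsv_checked(path, c("tf", "target", "mode", "likelihood"), "regulon")
  df$mode <- normalize_sign(df$mode)
  df$likelihood <- as.numeric(df$likelihood)
  if (any(df$likelihood <= 0 | df$likelihood > 1)) {
    stopf("regulon likelihood outside (0, 1] in %s", path)
  }
  out <- split(df[, c("target", "mode", "likelihood")], df$tf)
  for (tf in names(out)) {
    if (anyDuplicated(out[[tf]]$target)) stopf("duplicate target for TF %s", tf)
    rownames(out[[tf]]) <- NULL
  }
  out
}

#' @rdname read_regulons
#' @param regulons Named list of regulon data.frames.
#' @export
write_regulons <- function(regulons, path) {
  df <- do.call(rbind, lapply(names(regulons), function(tf) {
    cbind(tf = tf, regulons[[tf]])
  }))
  df$mode <- ifelse(df$mode > 0, "+1", "-1")
  write_tsv(df, path)
}

# Counts / metadata / tpm / gene stats ---------------------------------------

#' Read an RNA-seq count matrix
#'
#' @param path TSV, first column `gene_id`, remaining columns one sample
#'   each, non-negative integer counts.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path, "gene_id", "count matrix")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) stopf("counts must be non-negative integers: %s", path)
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  write_tsv(data.frame(gene_id = rownames(counts), counts, check.names = FALSE), path)
}

#' Read per-sample metadata
#'
#' @param path TSV with at least `sample_id`, `diagnosis`, `sex`,
#'   `region`, `dataset`; further numeric columns are treated as
#'   covariates (age, PMI, pH, RIN, ...).
#' @return Data.frame keyed by unique `sample_id`.
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "diagnosis", "sex", "region", "dataset"),
                         "sample metadata")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in %s", path)
  if (any(is.na(df$diagnosis)) || any(is.na(df$sex))) {
    stopf("diagnosis and sex must be non-missing in %s", path)
  }
  df
}

#' @rdname read_sample_meta
#' @param meta Data.frame of sample metadata.
#' @export
write_sample_meta <- function(meta, path) write_tsv(meta, path)

#' Read a tissue tpm table
#'
#' @param path TSV with columns `gene_id`, `tpm` (one tissue) or
#'   `gene_id` plus one column per tissue.
#' @return Data.frame.
#' @export
read_tpm <- function(path) read_tsv_checked(path, "gene_id", "tpm")

#' Read per-region TWAS gene statistics
#'
#' @param path TSV with columns `gene_id`, `region`, `zscore`, `pvalue`,
#'   `cv_r2`.
#' @return Data.frame of gene statistics (one row per gene x region).
#' @export
read_gene_stats <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "region", "zscore", "pvalue", "cv_r2"),
                         "TWAS gene statistics")
  for (col in c("zscore", "pvalue", "cv_r2")) df[[col]] <- as.numeric(df[[col]])
  bad <- is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  if (any(bad)) {
    pkg_log("warn", sprintf("read_gene_stats: dropped %d invalid row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_stats
#' @param stats Data.frame of gene statistics.
#' @export
write_gene_stats <- function(stats, path) write_tsv(stats, path)
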