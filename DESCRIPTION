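Package: twasmr
Title: Genome-to-Regulator Inference for Complex Trait Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline that chains GWAS summary-statistic gene
    aggregation (Fisher/Brown p-value combination with competitive and
    gene-property enrichment), cross-tissue TWAS integration with
    direction-consistency selection and Fisher meta-analysis,
    uncertainty-weighted regression and rank-based (GSEA) pathway
    enrichment, sex-stratified differential expression on RNA-seq counts
    with TMM normalization and covariate adjustment, and master-regulator
    inference on signed directed signaling networks via regulon-based
    transcription-factor activity scoring and signed shortest-path causal
    agreement. Includes a synthetic-data generator that plants ground
    truth (signal genes, enriched sets, sex-specific and sex-opposite
    differential expression, active and inactive regulators) so every
    stage is testable without protected external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
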