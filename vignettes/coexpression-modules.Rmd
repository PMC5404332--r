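---
title: "Co-expression modules in blood transcriptomes: methods and design"
author: "coexpmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules in blood transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpmod)
```

## The problem

Peripheral whole blood is the most accessible tissue for transcriptomic
studies of systemic disease, but it is a mixture: neutrophils, lymphocytes,
monocytes, eosinophils and basophils each carry their own expression
program, and their proportions shift with disease state. Single-gene
association scans in blood are therefore underpowered and confounded.
`coexpmod` implements the standard remedy: group genes into co-expression
modules, summarise each module by one latent score per sample (the
eigengene), relate those scores to a continuous clinical trait (here FEV1
percent predicted, the airflow-obstruction severity measure) with covariate
adjustment, and then ask two follow-up questions that the module view makes
answerable — does the module structure replicate in an independent cohort,
and which blood cell type does each module track?

## Model and procedure

**Network.** For genes $i,j$ with expression profiles over $n$ samples, the
network starts from Pearson correlation $r_{ij}$. Soft thresholding raises
it to a power: unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ (the default;
a signed variant $((1+r_{ij})/2)^\beta$ is available). $\beta$ is chosen as
the smallest integer for which the degree distribution approximates
scale-free topology: connectivity $k_i = \sum_{j \ne i} a_{ij}$ is binned
into 10 equal-width bins and $\log_{10} p(k)$ regressed on
$\log_{10} \bar k$; the fit index is $R^2$ signed by minus the slope, and
the default acceptance cut is 0.80. $\beta$ can also be fixed directly
(e.g. `beta = 7`) when the analyst has already chosen it.

**Topological overlap.** Adjacency is transformed into topological overlap
$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$
which rewards shared neighbourhoods and is more robust than raw
correlation. $1 - \mathrm{TOM}$ is the clustering dissimilarity.

**Modules.** Genes are clustered by average-linkage (UPGMA) hierarchical
clustering. Modules are read off the tree with a *static* cut placed at
`cut_height` (default 0.99) times the maximum merge height; branches below
the cut that contain at least `min_module_size` genes (default 30) become
modules, everything else is "grey" (unassigned). This is the "tree" variant
of tree cutting: deterministic and fully specified. The adaptive "hybrid"
dynamic cut used by some analyses handles nested or poorly separated
modules better and is a possible extension; for well-separated modules the
static cut recovers the same structure. An early design used the 0.99
*quantile of merge heights* as the cut; that variant degenerates whenever
unassigned background genes dominate, because their merges crowd the top
sliver of the tree and drag the quantile above the point where modules
attach — the height-fraction cut does not have this failure mode and is
what the package implements. Modules are named by the conventional color
sequence in decreasing size order (turquoise, blue, brown, ...).

**Eigengenes and membership.** A module's eigengene is the first principal
component of its standardized gene profiles, scaled to unit variance and
oriented to correlate positively with the module's mean expression. Module
membership (MM, also called kME) is the correlation between a gene and an
eigengene; the package reports the absolute value as MM (a 0–1 centrality
measure) and keeps the signed value for enrichment analysis. Eigengene
merging for near-duplicate modules (correlation above 0.75) is available
but off by default, since the baseline workflow does not merge.

**Trait association.** The trait is regressed on each predictor (gene or
eigengene) by OLS with adjustment covariates — age, sex (0/1, male = 1) and
pack-years in the discovery model; smoking status (one-hot, former as
reference) is added in cohorts that mix current and former smokers. The
direction (trait as response) sets the estimate scale to trait units per
unit predictor; eigengenes have unit variance, which makes module estimates
comparable. The optional cell-count adjustment adds the first three
principal components of the five blood cell percentages, which capture
essentially all compositional variance (the five percentages sum to ~100,
so the fifth component is degenerate). Benjamini–Hochberg correction is
applied within each scan, with the grey module never tested. The per-gene
scan is computed by Frisch–Waugh residualization, which is algebraically
identical to refitting the full model per gene and is verified against a
normal-equations oracle in the tests.

**Replication.** Module labels from discovery are frozen; eigengenes are
re-estimated in the replication cohort on the shared genes (at least 80%
of the module must be present) and sign-aligned to discovery through the
membership pattern, then tested against the trait with the replication
covariate set.

**Preservation.** Whether a module is "real" in the replication data is
measured by four statistics: two density statistics evaluated in the test
network (mean intramodular adjacency; proportion of variance explained by
the test-data eigengene) and two cross-network connectivity statistics
(correlation of intramodular connectivity vectors; correlation of the
vectorized correlation submatrices). Each observed statistic is
standardized against `n_permutations` (default 200) random gene sets of the
same size drawn from the shared gene universe:
$Z = (\mathrm{obs} - \mu_{\mathrm{perm}})/\sigma_{\mathrm{perm}}$.
`z_density` and `z_connectivity` are the medians within each family and
`Z_summary` is their mean; above 10 is conventionally strong preservation,
below 2 no evidence. A random "gold" module of up to 1000 genes provides
the whole-network baseline. This is a documented four-statistic subset of
the larger reference battery (medianRank and kME-based cross-tabulations
are not implemented); it covers both statistic families with fully
specified formulas.

**Cell-type attribution.** A purified-cell reference panel (e.g. nine
sorted immune cell subsets) is harmonized to the network's gene universe.
Each gene's reference profile is standardized across cell types into
specificity z-scores. For each module, the signed kME vector over all
shared network genes is Spearman-correlated with each cell type's
specificity scores; significance comes from shuffling the gene labels of
the score table (default 10,000 iterations), with the one-sided p-value
$(1 + \#\{\rho_{\mathrm{perm}} \ge \rho_{\mathrm{obs}}\})/(N+1)$ and the
best permuted rho reported as a yardstick. Correlating over *all* genes
(not only module members) is a deliberate choice: modules with a genuine
cell identity then produce large positive rho because non-members are
anti-correlated with both the eigengene and the cell's signature; a
module-genes-only variant is available behind a flag. Whether the
reference should be standardized across cell types before correlating is
genuinely open; the z-score form was chosen because it makes scores
comparable between highly and lowly expressed genes.

**Hub genes.** Within each module, genes are ranked twice — by MM
descending and by trait-association p-value ascending — and the hub order
is the ascending sum of ranks (average ranks for ties, then smaller p,
then gene id). Ranks are computed within-module, since hubs are meant to
be central to their module. Significant-gene subnetworks (top 50 genes
with FDR < 0.05 by default) export all pairwise TOM weights as edge lists
and GraphML with $-\log_{10} p$ node attributes.

## The synthetic-data generator

Because real cohort expression matrices and purified-cell reference
panels are external datasets, every stage is exercised on synthetic
studies with known truth. The generator plants
$K$ modules: module $k$ has a latent factor $f_k$ and its genes follow
$x_g = \lambda_k f_k + \sqrt{1-\lambda_k^2}\,\varepsilon$, so the expected
within-module correlation is exactly $\lambda_k^2$ — a closed form the
tests verify by Monte Carlo. Background genes are independent noise.
Designated modules are *cell-driven*: their factor is replaced by the
standardized fraction of a blood cell type, with per-sample fractions
drawn from a Dirichlet centered on a realistic differential (60/28/8/3/1
percent) with concentration 200, which keeps counts in the physiologic
range. The trait is a standardized linear combination of module factors,
standardized covariates and noise, rescaled to mean 49.5 and SD 16.2
(FEV1 percent predicted in a severe-COPD population); covariates are drawn
at age 64 ± 6, 64% male, 46 ± 27 pack-years. Discovery (default n = 238,
all former smokers) and replication (n = 381, mixed former/current, with
an optional never-smoker control stratum at 109.7 ± 15.8) are independent
draws from the same gene model, with all sub-seeds derived from one master
seed. A matched purified-cell reference gives each module's genes a mean
shift (default 2 SD) in its mapped cell type — the CBC type for
cell-driven modules, otherwise a distinct unused type round-robin — so
enrichment has a planted ground truth.

What the generator does *not* emulate: probe-level microarray noise, batch
effects, missing values, correlated background genes, within-module
variation in membership strength (all genes in a module share one
$\lambda_k$), or heavy-tailed expression. Passing tests therefore
demonstrate correctness of the algorithms under a clean factor model, not
robustness to real microarray artefacts. The equal-loadings choice has one
visible consequence: within a planted module the intramodular connectivity
differences are pure noise, so the connectivity preservation statistics
carry no signal for planted modules (their Z can even be negative, because
random gene sets straddling module boundaries do have reproducible
connectivity patterns); the density statistics dominate Z-summary in
simulation, and monotonicity of preservation in $\lambda$ is asserted on
the density family. A related consequence: a block factor model plus
independent noise does not produce a scale-free degree distribution, so on
synthetic data the soft-threshold selection criterion often fails to reach
its R² cut and falls back (flagged) to the argmax power — the criterion is
informative on real transcriptomes, whose correlation structure is
hierarchical, and the unit tests therefore check the selection *contract*
(smallest qualifying power, fallback behavior, monotone mean connectivity)
rather than a particular chosen value.

## Numerical choices and defaults

* Default soft power `beta = 7` with `1:20` as the candidate grid and a
  0.80 signed-R² cut when selection is requested; 10 equal-width
  connectivity bins, at least 3 nonempty bins required for a fit.
* Unsigned network by default; the unsigned/signed choice is exposed
  because either is defensible (signed networks separate anti-correlated
  modules — in blood, compositionally anti-correlated cell types — at the
  cost of halving effective correlations).
* TOM values are clamped to $[0,1]$ against floating-point drift and
  symmetrized; the diagonal is 1 by convention.
* Static cut at 0.99 of maximum merge height, minimum module size 30;
  sub-threshold branches become grey rather than being rescued.
* Module size ties in the color ordering break on the lexicographically
  smallest member gene id, making labels invariant to gene order.
* Eigengene sign: positive correlation with the module's mean standardized
  profile; single-gene modules return the standardized profile with a
  warning.
* OLS uses listwise deletion and refuses rank-deficient designs by naming
  the collinear columns; p-values are two-sided t-tests.
* Permutation p-values use the +1 correction in numerator and denominator,
  so the minimum attainable p is $1/(N+1)$ and zero never occurs.
* Zero permutation SD in preservation sets that Z to $+\infty$ with a
  warning rather than failing.
* All randomness flows through explicit seeds; `run_pipeline()` re-runs
  bit-identically for a fixed config (the JSON metadata file records
  per-stage wall times and is exempt).

## Problem sizes used in validation

The bundled checks run planted-recovery at 2250 genes (5 modules of 50
plus 2000 background, $\lambda = 0.8$, n = 200, 10 seeds), trait-module
replication at 1250 genes with cohort sizes 238/381 and a module effect
calibrated to 5% of trait variance, preservation at 800 genes with 200
permutations, and enrichment with 1000-iteration permutation tests. These
sizes were chosen so the full validation completes in minutes while
keeping every rate estimate away from its decision boundary; the
algorithms themselves are dense-matrix implementations comfortable up to a
few tens of thousands of genes.

## A short worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
fit <- coexp_fit(study$expr_discovery, beta = 7)
summary(fit)

disc <- module_trait_scan(fit, study$pheno_discovery)
head(disc)

eg_rep <- predict(fit, study$expr_replication)
repl <- module_trait_scan(eg_rep, study$pheno_replication,
                          covariates = c("age", "sex", "pack_years",
                                         "smoking_status"))

pres <- module_preservation(study$expr_discovery, study$expr_replication,
                            fit$colors, beta = 7, seed = 1)
plot(pres)

enr <- cell_enrichment(fit, study$cell_reference, seed = 1)
subset(enr, module == enr$module[1])
```

## Known limitations

* Static tree cut only; deeply nested module structure needs the hybrid
  dynamic cut.
* Dense matrices throughout: memory is quadratic in gene count, and the
  TOM of ~50k genes is out of reach without blocking.
* Four preservation statistics rather than the full reference battery;
  medianRank is not available as a size-robust companion to Z-summary.
* Pearson correlation only (no biweight midcorrelation), so single-sample
  outliers can inflate adjacency.
* The generator's clean factor model understates the difficulty of real
  tree cutting, where module boundaries are gradual.
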