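# coexpmod

Weighted gene co-expression module analysis for peripheral-blood
transcriptomes, with a built-in synthetic-data generator.

`coexpmod` is for analysts relating blood gene expression to a continuous
clinical trait (the motivating use case is FEV₁ % predicted, the airflow
obstruction severity measure in COPD) when single-gene scans are
underpowered and confounded by blood cell composition. Instead of testing
19,000 genes one at a time, it:

1. builds a weighted co-expression network — Pearson correlation, soft
   thresholding (`a_ij = |r_ij|^β`, β chosen by the scale-free topology
   criterion or fixed), topological overlap
   `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)`;
2. detects modules by average-linkage clustering of `1 − TOM` with a static
   tree cut and minimum module size, names them by the canonical color
   sequence, and summarises each by its **eigengene** (first principal
   component, unit variance) and per-gene **module membership** (kME);
3. regresses the trait on each eigengene with adjustment for age, sex and
   pack-years — optionally adding the first three principal components of
   the five blood cell percentages — with Benjamini–Hochberg FDR;
4. tests **replication**: eigengenes are re-estimated in an independent
   cohort from the frozen discovery gene sets and re-tested;
5. tests **module preservation** with permutation Z statistics (density
   and connectivity families, combined into Z_summary; > 10 is strong
   preservation) against a random "gold" module baseline;
6. attributes modules to **blood cell types** by Spearman correlation of
   signed kME with cell-specificity z-scores from a purified-cell
   reference panel, permutation-tested;
7. ranks **hub genes** by the sum of module-membership and
   gene-significance ranks, and exports hub subnetworks as edge lists and
   GraphML.

Because realistic inputs (cohort expression matrices, purified-cell
reference panels) are external datasets, the package ships a generator (`simulate_study()`) that plants co-expressed
modules (`x = λf + √(1−λ²)ε`, so within-module correlation is exactly
λ²), cell-composition confounding via Dirichlet cell fractions, a trait
driven by module factors and covariates, paired discovery/replication
cohorts, and a matched cell reference — every stage is testable against
known truth.

## Worked example

```r
library(coexpmod)

study <- simulate_study(sim_config(
  n_genes = 1000, module_sizes = rep(50, 4),
  trait_effects = c(-0.4, 0.3, 0, 0),
  cell_driven_modules = c("1" = "neutrophil"),
  n_samples_discovery = 238, n_samples_replication = 381, seed = 1))

fit <- coexp_fit(study$expr_discovery, beta = 7)
fit
#> Weighted co-expression module fit
#>   1000 genes x 238 samples, unsigned network, beta = 7
#>   4 modules (200 genes assigned, 800 grey)
#>   largest: blue (50), brown (50), turquoise (50), yellow (50)

module_trait_scan(fit, study$pheno_discovery)
#>   feature_id estimate    se  p_value      fdr n_used
#> 3  turquoise    -5.64 0.961 1.52e-08 6.06e-08    238
#> 1       blue     3.57 0.979 3.26e-04 6.53e-04    238
#> 2      brown    -2.20 1.005 2.93e-02 3.91e-02    238
#> 4     yellow     1.49 0.999 1.37e-01 1.37e-01    238
```

The turquoise module is the planted neutrophil-driven module with a −0.4
trait effect: its eigengene costs 5.6 trait units (FEV₁ % predicted) per
unit score. Adding the three cell-count PCs wipes out exactly that module
— the association was carried by cell composition:

```r
module_trait_scan(fit, study$pheno_discovery, adjust_cells = TRUE)
#>   feature_id estimate  p_value    fdr
#> 1       blue     3.37 0.000326 0.0013
#> 2      brown    -2.09 0.029623 0.0592
#> 4     yellow     1.26 0.187075 0.2494
#> 3  turquoise    -9.81 0.258489 0.2585
```

Replication (eigengenes projected into the second cohort, smoking status
added to the model) confirms the two real trait modules; preservation
Z_summary is far above 10 for every planted module and near zero for the
random gold module; and the cell reference attributes turquoise to
neutrophils:

```r
eg_rep <- predict(fit, study$expr_replication)
module_trait_scan(eg_rep, study$pheno_replication,
                  covariates = c("age", "sex", "pack_years", "smoking_status"))
#>   feature_id estimate    se  p_value      fdr
#> 3  turquoise   -7.059 0.729 6.03e-20 2.41e-19
#> 1       blue    5.459 0.764 4.81e-12 9.62e-12
#> 2      brown   -0.706 0.818 3.89e-01 5.18e-01
#> 4     yellow    0.294 0.815 7.18e-01 7.18e-01

module_preservation(study$expr_discovery, study$expr_replication,
                    fit$colors, beta = 7, n_permutations = 200,
                    seed = 1, gold_size = 500)$summary
#>      module size z_density z_connectivity z_summary
#> 1      blue   50  114.6325       -7.40413   53.6142
#> 2     brown   50   90.8293      -15.51801   37.6556
#> 3 turquoise   50  103.5830       -7.73545   47.9238
#> 4    yellow   50   93.3428      -17.12689   38.1079
#> 5      gold  500    0.1531        0.09647    0.1248

head(subset(cell_enrichment(fit, study$cell_reference, seed = 1),
            module == "turquoise"), 3)
#>       module   cell_type    rho perm_p best_perm_rho n_permutations
#> 12 turquoise neutrophils 0.1011 0.0006         0.109          10000
#> 82 turquoise        mDCs 0.0288 0.1813         0.110          10000
#> 62 turquoise CD4_T_cells 0.0177 0.2892         0.119          10000
```

`run_pipeline(run_config(out_dir = "my_run"))` executes all of the above
(plus gene-level scans and hub/GraphML export) from a single serializable
configuration and writes every stage's table with a config-hash stamp;
re-running a config reproduces all outputs bit-identically. A thin CLI
wrapper lives at `inst/cli/coexpmod.R`. See the vignette
(`vignettes/coexpression-modules.Rmd`) for the model, the generator's
assumptions, and every default's rationale.

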