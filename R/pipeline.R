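# End-to-end pipeline: simulate (or load) -> fit network/modules ->
# associate (+/- cell adjustment) -> replicate -> preserve -> enrich ->
# hubs, with every output written to a directory and a JSON metadata file.

#' Pipeline configuration
#'
#' Collects every stage's parameters into a single serializable list.
#' Either provide `expression`/`phenotype` (+ replication) file paths, or
#' leave them `NULL` to simulate a study from `sim` at run time.
#'
#' @param out_dir Output directory (created if absent).
#' @param expression,phenotype,expression_replication,phenotype_replication
#'   Input file paths, or `NULL` to simulate.
#' @param cell_reference Path to a gene-by-cell-type reference table, or
#'   `NULL` (simulated study provides its own).
#' @param sim A [sim_config()] (used only when inputs are `NULL`).
#' @param beta Soft power; `NULL` picks it by scale-free fit.
#' @param r2_cut,signed,cut_height,min_module_size Network and
#'   tree-cut parameters (see [coexp_fit()]).
#' @param adjust_cells Also run cell-count-adjusted association scans.
#' @param n_permutations_preservation,n_permutations_enrichment,gold_size
#'   Permutation settings.
#' @param hub_top_n,hub_fdr_cut Subnetwork export settings.
#' @param seed Master seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       expression = NULL, phenotype = NULL,
                       expression_replication = NULL,
                       phenotype_replication = NULL,
                       cell_reference = NULL,
                       sim = sim_config(),
                       beta = 7L, r2_cut = 0.80, signed = FALSE,
                       cut_height = 0.99, min_module_size = 30L,
                       adjust_cells = TRUE,
                       n_permutations_preservation = 200L,
                       n_permutations_enrichment = 1000L,
                       gold_size = 1000L,
                       hub_top_n = 50L, hub_fdr_cut = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$sim <- unclass(sim)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments
#'   (nested `sim:` block for the simulation settings).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  y$sim <- sim
  do.call(run_config, y)
}

# Hash of the analysis-defining parameters; out_dir is excluded so the same
# analysis written to two places carries the same stamp.
#' @keywords internal
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full co-expression module pipeline
#'
#' Executes simulate/load, network + module fitting, gene- and module-level
#' trait association (with and, when configured, without cell-count
#' adjustment), eigengene projection and association in the replication
#' cohort, permutation module preservation, cell-type enrichment and hub
#' scoring. Every stage's table is written tab-separated to
#' `config$out_dir`, each prefixed with a comment line carrying the config
#' hash; `run_metadata.json` records package version, seeds, parameters and
#' per-stage wall times. With a fixed config all outputs are reproduced
#' bit-identically on re-run (the metadata file, which contains timings, is
#' the one exception).
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory stage results and
#'   `output_files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  tag <- paste0("coexpmod config ", hash)
  times <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  outp <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  # --- inputs ---------------------------------------------------------
  t0 <- tic()
  if (is.null(config$expression)) {
    sim <- do.call(sim_config, config$sim)
    study <- simulate_study(sim)
    expr <- study$expr_discovery; pheno <- study$pheno_discovery
    expr_rep <- study$expr_replication; pheno_rep <- study$pheno_replication
    reference <- study$cell_reference
    write_expression(expr, outp("expression_discovery.tsv"), tag)
    write_expression(expr_rep, outp("expression_replication.tsv"), tag)
    write_tsv(pheno, outp("phenotype_discovery.tsv"), tag)
    write_tsv(pheno_rep, outp("phenotype_replication.tsv"), tag)
    write_tsv(data.frame(gene_id = names(study$true_labels),
                         module = study$true_labels),
              outp("true_labels.tsv"), tag)
    write_expression(reference, outp("cell_reference.tsv"), tag)
    files <- c(files, "expression_discovery.tsv", "expression_replication.tsv",
               "phenotype_discovery.tsv", "phenotype_replication.tsv",
               "true_labels.tsv", "cell_reference.tsv")
  } else {
    expr <- read_expression(config$expression)
    pheno <- read_phenotype(config$phenotype)
    expr_rep <- if (!is.null(config$expression_replication))
      read_expression(config$expression_replication) else NULL
    pheno_rep <- if (!is.null(config$phenotype_replication))
      read_phenotype(config$phenotype_replication) else NULL
    reference <- if (!is.null(config$cell_reference))
      read_cell_reference(config$cell_reference) else NULL
  }
  times$inputs <- lap(t0)

  # --- network + modules ---------------------------------------------
  t0 <- tic()
  fit <- coexp_fit(expr, beta = config$beta, r2_cut = config$r2_cut,
                   signed = config$signed,
                   cut_height = config$cut_height,
                   min_module_size = config$min_module_size,
                   keep_tom = TRUE)
  has_modules <- any(fit$labels > 0L)
  if (!has_modules)
    warning("no module detected; module-level stages are skipped")
  write_tsv(data.frame(gene_id = fit$gene_ids, module = fit$colors),
            outp("module_labels.tsv"), tag)
  files <- c(files, "module_labels.tsv")
  if (has_modules) {
    write_tsv(data.frame(sample_id = rownames(fit$eigengenes),
                         fit$eigengenes, check.names = FALSE),
              outp("eigengenes_discovery.tsv"), tag)
    write_tsv(data.frame(gene_id = fit$gene_ids, fit$mm, check.names = FALSE),
              outp("module_membership.tsv"), tag)
    files <- c(files, "eigengenes_discovery.tsv", "module_membership.tsv")
  }
  if (!is.null(fit$power_fits)) {
    write_tsv(fit$power_fits, outp("soft_threshold_fits.tsv"), tag)
    files <- c(files, "soft_threshold_fits.tsv")
  }
  times$network_modules <- lap(t0)

  # --- association ----------------------------------------------------
  t0 <- tic()
  gene_assoc <- gene_trait_scan(expr, pheno)
  write_tsv(gene_assoc, outp("gene_association.tsv"), tag)
  files <- c(files, "gene_association.tsv")
  mod_assoc <- gene_assoc_cells <- mod_assoc_cells <- NULL
  if (has_modules) {
    mod_assoc <- module_trait_scan(fit$eigengenes, pheno)
    write_tsv(mod_assoc, outp("module_association.tsv"), tag)
    files <- c(files, "module_association.tsv")
  }
  if (isTRUE(config$adjust_cells)) {
    gene_assoc_cells <- gene_trait_scan(expr, pheno, adjust_cells = TRUE)
    write_tsv(gene_assoc_cells, outp("gene_association_celladj.tsv"), tag)
    files <- c(files, "gene_association_celladj.tsv")
    if (has_modules) {
      mod_assoc_cells <- module_trait_scan(fit$eigengenes, pheno,
                                           adjust_cells = TRUE)
      write_tsv(mod_assoc_cells, outp("module_association_celladj.tsv"), tag)
      files <- c(files, "module_association_celladj.tsv")
    }
  }
  times$association <- lap(t0)

  # --- replication ----------------------------------------------------
  rep_assoc <- preservation <- NULL
  if (!is.null(expr_rep) && has_modules) {
    t0 <- tic()
    eg_rep <- predict(fit, expr_rep)
    covs <- c("age", "sex", "pack_years",
              if (length(unique(pheno_rep$smoking_status)) > 1L)
                "smoking_status")
    rep_assoc <- module_trait_scan(eg_rep, pheno_rep, covariates = covs)
    write_tsv(data.frame(sample_id = rownames(eg_rep), eg_rep,
                         check.names = FALSE),
              outp("eigengenes_replication.tsv"), tag)
    write_tsv(rep_assoc, outp("module_association_replication.tsv"), tag)
    files <- c(files, "eigengenes_replication.tsv",
               "module_association_replication.tsv")
    times$replication <- lap(t0)

    t0 <- tic()
    preservation <- module_preservation(
      expr, expr_rep, fit$colors, beta = fit$beta, signed = config$signed,
      n_permutations = config$n_permutations_preservation,
      seed = config$seed, gold_size = config$gold_size)
    write_tsv(preservation$summary, outp("preservation.tsv"), tag)
    files <- c(files, "preservation.tsv")
    times$preservation <- lap(t0)
  }

  # --- enrichment -----------------------------------------------------
  enrichment <- NULL
  if (!is.null(reference) && has_modules) {
    t0 <- tic()
    enrichment <- cell_enrichment(
      fit, reference, n_permutations = config$n_permutations_enrichment,
      seed = config$seed)
    write_tsv(enrichment, outp("cell_enrichment.tsv"), tag)
    files <- c(files, "cell_enrichment.tsv")
    times$enrichment <- lap(t0)
  }

  # --- hubs -----------------------------------------------------------
  t0 <- tic()
  hubs <- NULL
  if (has_modules) {
  gs_p <- stats::setNames(gene_assoc$p_value, gene_assoc$feature_id)
  gs_fdr <- stats::setNames(gene_assoc$fdr, gene_assoc$feature_id)
  hubs <- lapply(module_names(fit$colors), function(m) {
    genes <- fit$gene_ids[fit$colors == m]
    cbind(module = m, hub_scores(genes, stats::setNames(fit$mm[, m],
                                                        fit$gene_ids), gs_p),
          stringsAsFactors = FALSE)
  })
  hubs <- do.call(rbind, hubs)
  write_tsv(hubs, outp("hub_genes.tsv"), tag)
  files <- c(files, "hub_genes.tsv")
  for (m in module_names(fit$colors)) {
    genes <- fit$gene_ids[fit$colors == m]
    net <- withCallingHandlers(
      export_module_network(fit$tom, genes, gs_p, gs_fdr,
                            top_n = config$hub_top_n,
                            fdr_cut = config$hub_fdr_cut),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(net$nodes)) {
      write_tsv(net$edges, outp(paste0("network_", m, "_edges.tsv")), tag)
      write_module_graphml(net, outp(paste0("network_", m, ".graphml")),
                           module = m,
                           mm = stats::setNames(fit$mm[, m], fit$gene_ids))
      files <- c(files, paste0("network_", m, "_edges.tsv"),
                 paste0("network_", m, ".graphml"))
    }
  }
  }
  times$hubs <- lap(t0)

  meta <- list(package = "coexpmod",
               version = as.character(utils::packageVersion("coexpmod")),
               r_version = R.version.string,
               config_hash = hash,
               config = unclass(config),
               beta_used = fit$beta,
               stage_seconds = times,
               outputs = files)
  jsonlite::write_json(meta, outp("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE, force = TRUE)

  invisible(list(fit = fit, gene_association = gene_assoc,
                 module_association = mod_assoc,
                 gene_association_celladj = gene_assoc_cells,
                 module_association_celladj = mod_assoc_cells,
                 replication_association = rep_assoc,
                 preservation = preservation, enrichment = enrichment,
                 hubs = hubs, config_hash = hash,
                 output_files = file.path(config$out_dir, files)))
}
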