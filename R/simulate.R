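# Synthetic paired-cohort generator with planted co-expression modules,
# cell-composition confounding and a matched purified-cell reference.

#' Simulation configuration
#'
#' Defines a two-cohort blood transcriptome study with planted co-expressed
#' modules. Each module k has a latent factor f_k; genes in the module follow
#' x = lambda_k * f_k + sqrt(1 - lambda_k^2) * noise, so the expected
#' within-module gene-gene correlation is lambda_k^2. Modules listed in
#' `cell_driven_modules` replace f_k by the standardized fraction of a blood
#' cell type, which makes them confounded with the complete blood count.
#' The clinical trait (FEV1 percent predicted) is a standardized linear
#' combination of module factors, covariates and noise, rescaled to
#' `trait_mean`/`trait_sd`.
#'
#' Cohort sizes default to 238 and 381 and the trait to mean 49.5, sd 16.2 —
#' typical of a moderate-to-severe COPD population; covariate distributions
#' (age 64 +/- 6 years, 64 percent male, 46 +/- 27 pack-years) match the same
#' setting.
#'
#' @param n_genes Total genes, planted modules plus background.
#' @param n_samples_discovery,n_samples_replication Cohort sizes.
#' @param module_sizes Integer vector of planted module sizes; must sum to
#'   at most `n_genes`, remaining genes are i.i.d. background noise.
#' @param loadings Per-module factor loading lambda in (0,1); recycled.
#' @param trait_effects Per-module trait coefficient beta (on the
#'   standardized-factor scale); recycled.
#' @param trait_mean,trait_sd Trait location/scale in FEV1 \%pred units.
#' @param covariate_effects Named numeric: effects of standardized age, sex
#'   and pack-years on the trait's linear predictor.
#' @param cell_base_fractions Five nonnegative fractions (neutrophil,
#'   lymphocyte, monocyte, eosinophil, basophil) summing to 1.
#' @param dirichlet_concentration Dirichlet precision; per-sample cell
#'   fractions are drawn from Dirichlet(concentration * base_fractions).
#'   The default 200 keeps differentials in the physiologic range.
#' @param cell_driven_modules Named integer-to-cell-type map, e.g.
#'   `c("1" = "neutrophil")`: module 1's factor becomes the standardized
#'   neutrophil fraction.
#' @param reference_cell_types Cell-type names of the purified-cell
#'   reference panel.
#' @param reference_specificity Mean shift added to a module's genes in its
#'   mapped reference cell type (round-robin when a module has no mapped
#'   type); unit-variance noise elsewhere.
#' @param noise_sd Trait residual noise sd (linear-predictor scale).
#' @param include_controls Add a never-smoker control stratum to the
#'   replication cohort (trait 109.7 +/- 15.8); off by default.
#' @param n_controls Control stratum size when enabled.
#' @param seed Master seed; all draws derive deterministically from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2250L,
                       n_samples_discovery = 238L,
                       n_samples_replication = 381L,
                       module_sizes = rep(50L, 5L),
                       loadings = 0.8,
                       trait_effects = c(-0.35, 0.3, 0.3, 0, 0),
                       trait_mean = 49.5,
                       trait_sd = 16.2,
                       covariate_effects = c(age = -0.15, sex = 0.1, pack_years = -0.2),
                       cell_base_fractions = c(neutrophil = 0.60, lymphocyte = 0.28,
                                               monocyte = 0.08, eosinophil = 0.03,
                                               basophil = 0.01),
                       dirichlet_concentration = 200,
                       cell_driven_modules = c("1" = "neutrophil", "2" = "lymphocyte"),
                       reference_cell_types = c("neutrophils", "eosinophils", "monocytes",
                                                "B_cells", "NK_cells", "CD4_T_cells",
                                                "CD8_T_cells", "mDCs", "pDCs"),
                       reference_specificity = 2,
                       noise_sd = 1,
                       include_controls = FALSE,
                       n_controls = 58L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_discovery = as.integer(n_samples_discovery),
    n_samples_replication = as.integer(n_samples_replication),
    module_sizes = as.integer(module_sizes),
    loadings = rep_len(loadings, length(module_sizes)),
    trait_effects = rep_len(trait_effects, length(module_sizes)),
    trait_mean = trait_mean, trait_sd = trait_sd,
    covariate_effects = covariate_effects,
    cell_base_fractions = cell_base_fractions,
    dirichlet_concentration = dirichlet_concentration,
    cell_driven_modules = cell_driven_modules,
    reference_cell_types = reference_cell_types,
    reference_specificity = reference_specificity,
    noise_sd = noise_sd,
    include_controls = isTRUE(include_controls),
    n_controls = as.integer(n_controls),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("invalid 'module_sizes': sum exceeds n_genes", call. = FALSE)
  if (any(cfg$module_sizes < 2L))
    stop("invalid 'module_sizes': each module needs >= 2 genes", call. = FALSE)
  if (any(cfg$loadings <= 0 | cfg$loadings >= 1))
    stop("invalid 'loadings': each lambda must lie in (0,1)", call. = FALSE)
  if (cfg$n_samples_discovery < 10L || cfg$n_samples_replication < 10L)
    stop("invalid sample sizes: need >= 10 per cohort", call. = FALSE)
  if (any(cfg$cell_base_fractions < 0) ||
      abs(sum(cfg$cell_base_fractions) - 1) > 1e-9)
    stop("invalid 'cell_base_fractions': must be nonnegative and sum to 1",
         call. = FALSE)
  if (length(cfg$cell_base_fractions) != 5L)
    stop("invalid 'cell_base_fractions': exactly five cell types expected",
         call. = FALSE)
  if (length(cfg$cell_driven_modules)) {
    bad <- setdiff(cfg$cell_driven_modules, names(cfg$cell_base_fractions))
    if (length(bad))
      stop("invalid 'cell_driven_modules': unknown cell type ", bad[1],
           call. = FALSE)
    idx <- as.integer(names(cfg$cell_driven_modules))
    if (anyNA(idx) || any(idx < 1L | idx > length(cfg$module_sizes)))
      stop("invalid 'cell_driven_modules': module index out of range",
           call. = FALSE)
  }
  if (cfg$noise_sd <= 0)
    stop("invalid 'noise_sd': must be positive", call. = FALSE)
  invisible(cfg)
}

# Dirichlet via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# CBC cell type -> reference panel cell type, where a direct counterpart
# exists; lymphocytes map to CD4 T cells as the dominant lymphocyte subset.
cbc_to_reference <- c(neutrophil = "neutrophils", eosinophil = "eosinophils",
                      monocyte = "monocytes", lymphocyte = "CD4_T_cells")

simulate_cohort <- function(cfg, n, seed, cohort, smoking = "former") {
  set.seed(seed)
  k <- length(cfg$module_sizes)
  ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  samples <- sprintf("%s_S%03d", cohort, seq_len(n))

  frac <- rdirichlet(n, cfg$dirichlet_concentration * cfg$cell_base_fractions)
  age <- stats::rnorm(n, 64, 6)
  sex <- stats::rbinom(n, 1L, 0.64)
  pack_years <- pmax(0, stats::rnorm(n, 46, 27))
  smoking_status <- if (length(smoking) == 1L) rep(smoking, n) else
    sample(names(smoking), n, replace = TRUE, prob = smoking)

  f <- matrix(stats::rnorm(n * k), n, k)
  for (m in names(cfg$cell_driven_modules))
    f[, as.integer(m)] <- standardize(frac[, cfg$cell_driven_modules[[m]]])

  expr <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                 dimnames = list(ids, samples))
  offset <- 0L
  for (j in seq_len(k)) {
    rows <- offset + seq_len(cfg$module_sizes[j])
    lam <- cfg$loadings[j]
    expr[rows, ] <- lam * matrix(f[, j], cfg$module_sizes[j], n, byrow = TRUE) +
      sqrt(1 - lam^2) * expr[rows, ]
    offset <- offset + cfg$module_sizes[j]
  }

  eta <- drop(f %*% cfg$trait_effects) +
    cfg$covariate_effects[["age"]] * standardize(age) +
    cfg$covariate_effects[["sex"]] * (sex - mean(sex)) +
    cfg$covariate_effects[["pack_years"]] * standardize(pack_years) +
    cfg$noise_sd * stats::rnorm(n)
  trait <- cfg$trait_mean + cfg$trait_sd * standardize(eta)

  pheno <- data.frame(
    sample_id = samples, fev1pp = trait, age = age, sex = sex,
    pack_years = pack_years, smoking_status = smoking_status,
    neut_pct = 100 * frac[, "neutrophil"], lymph_pct = 100 * frac[, "lymphocyte"],
    mono_pct = 100 * frac[, "monocyte"], eos_pct = 100 * frac[, "eosinophil"],
    baso_pct = 100 * frac[, "basophil"],
    stringsAsFactors = FALSE
  )
  list(expr = expr, pheno = pheno, factors = f)
}

#' Simulate a paired discovery/replication co-expression study
#'
#' Draws two independent cohorts from the generative model in
#' [sim_config()], plus a purified-cell reference expression table in which
#' each planted module's genes are up-shifted in the module's mapped cell
#' type. The discovery cohort is all former smokers; the replication cohort
#' mixes former and current smokers (and optionally never-smoker controls
#' whose trait is drawn at 109.7 +/- 15.8).
#'
#' @param config A [sim_config()] object.
#' @return A `simulated_study` list: `expr_discovery`, `expr_replication`
#'   (genes x samples matrices), `pheno_discovery`, `pheno_replication`
#'   (data frames; columns sample_id, fev1pp, age, sex, pack_years,
#'   smoking_status and the five cell percentages), `true_labels`
#'   (named integer vector, 0 = background), `true_trait_modules`,
#'   `factors_discovery`/`factors_replication` (latent factors, for
#'   validation), `cell_reference` (genes x cell types), and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_genes = 300, module_sizes = c(40, 40),
#'                                    n_samples_discovery = 60,
#'                                    n_samples_replication = 60, seed = 7))
#' table(study$true_labels)
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 4L)

  disc <- simulate_cohort(config, config$n_samples_discovery, seeds[1], "DISC")
  repl <- simulate_cohort(config, config$n_samples_replication, seeds[2], "REPL",
                          smoking = c(former = 0.585, current = 0.415))

  if (config$include_controls) {
    set.seed(seeds[4])
    ctl <- simulate_cohort(config, config$n_controls, seeds[4], "CTRL",
                           smoking = "never")
    set.seed(seeds[4] %% 1000003L + 1L)
    ctl$pheno$fev1pp <- stats::rnorm(config$n_controls, 109.7, 15.8)
    ctl$pheno$pack_years <- 0
    repl$expr <- cbind(repl$expr, ctl$expr)
    repl$pheno <- rbind(repl$pheno, ctl$pheno)
  }

  labels <- rep(0L, config$n_genes)
  names(labels) <- rownames(disc$expr)
  offset <- 0L
  for (j in seq_along(config$module_sizes)) {
    labels[offset + seq_len(config$module_sizes[j])] <- j
    offset <- offset + config$module_sizes[j]
  }

  # Reference: unit noise + specificity shift of module genes in the mapped
  # (or round-robin) reference cell type.
  set.seed(seeds[3])
  ref <- matrix(stats::rnorm(config$n_genes * length(config$reference_cell_types)),
                config$n_genes, length(config$reference_cell_types),
                dimnames = list(names(labels), config$reference_cell_types))
  module_ref_type <- character(length(config$module_sizes))
  for (j in seq_along(config$module_sizes)) {
    cbc <- if (as.character(j) %in% names(config$cell_driven_modules))
      config$cell_driven_modules[[as.character(j)]] else NULL
    if (!is.null(cbc) && cbc %in% names(cbc_to_reference) &&
        cbc_to_reference[[cbc]] %in% config$reference_cell_types) {
      module_ref_type[j] <- cbc_to_reference[[cbc]]
    }
  }
  # unmapped modules take distinct, not-yet-used reference types round-robin
  free <- setdiff(config$reference_cell_types, module_ref_type)
  for (j in seq_along(module_ref_type)) {
    if (module_ref_type[j] == "") {
      if (!length(free)) free <- config$reference_cell_types
      module_ref_type[j] <- free[1L]
      free <- free[-1L]
    }
  }
  for (j in seq_along(config$module_sizes)) {
    type <- module_ref_type[j]
    ref[labels == j, type] <- ref[labels == j, type] + config$reference_specificity
  }

  structure(list(
    expr_discovery = disc$expr, expr_replication = repl$expr,
    pheno_discovery = disc$pheno, pheno_replication = repl$pheno,
    true_labels = labels,
    true_trait_modules = which(config$trait_effects != 0),
    module_reference_type = module_ref_type,
    factors_discovery = disc$factors, factors_replication = repl$factors,
    cell_reference = ref, config = config
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulated co-expression study\n")
  cat(sprintf("  genes: %d (%d in %d planted modules, %d background)\n",
              cfg$n_genes, sum(cfg$module_sizes), length(cfg$module_sizes),
              cfg$n_genes - sum(cfg$module_sizes)))
  cat(sprintf("  samples: %d discovery / %d replication\n",
              ncol(x$expr_discovery), ncol(x$expr_replication)))
  cat(sprintf("  trait-linked modules: %s; cell-driven: %s\n",
              paste(x$true_trait_modules, collapse = ","),
              if (length(cfg$cell_driven_modules))
                paste(names(cfg$cell_driven_modules), cfg$cell_driven_modules,
                      sep = ">", collapse = ", ") else "none"))
  invisible(x)
}
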