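# Trait association: covariate-adjusted OLS at the gene and module level,
# cell-count principal components, Benjamini-Hochberg correction.

#' Covariate-adjusted linear association of a trait with one predictor
#'
#' Ordinary least squares of `y` on an intercept, `x` and the covariate
#' columns; returns the coefficient on `x` with its standard error and
#' two-sided t-test p-value. Rows with missing values are dropped listwise.
#'
#' @param y Numeric response (the trait).
#' @param x Numeric predictor (gene expression or module eigengene).
#' @param covariates Optional numeric matrix/data frame of adjustment
#'   covariates.
#' @return List: `estimate`, `se`, `p_value`, `n_used`.
#' @export
linear_association <- function(y, x, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  n <- length(y)
  if (length(x) != n || (!is.null(covariates) && nrow(covariates) != n))
    stop("y, x and covariates must have the same number of rows", call. = FALSE)
  keep <- stats::complete.cases(y, x, covariates)
  y <- y[keep]; x <- x[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  p_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (length(y) <= p_cov + 2L)
    stop("too few complete observations (", length(y), ") for ",
         p_cov, " covariates", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tval <- cf[["x"]] / se
  list(estimate = cf[["x"]], se = se,
       p_value = 2 * stats::pt(-abs(tval), df), n_used = length(y))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p Vector of p-values in (0, 1].
#' @return Step-up adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0,1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Principal components of the five blood cell percentages
#'
#' Column-centers the neutrophil/lymphocyte/monocyte/eosinophil/basophil
#' percentages and extracts principal components by singular value
#' decomposition. Because the percentages are compositional (near-constant
#' sum), the last component carries essentially no variance. Component signs
#' follow the convention that the loading largest in absolute value is
#' positive.
#'
#' @param pheno Phenotype data frame with columns `neut_pct`, `lymph_pct`,
#'   `mono_pct`, `eos_pct`, `baso_pct`.
#' @param n_components Number of score columns to return (default 3).
#' @return List: `scores` (samples x n_components), `variance_explained`
#'   (cumulative fraction for the returned components), `loadings`.
#' @export
cell_count_pcs <- function(pheno, n_components = 3L) {
  cols <- c("neut_pct", "lymph_pct", "mono_pct", "eos_pct", "baso_pct")
  miss <- setdiff(cols, names(pheno))
  if (length(miss))
    stop("phenotype table lacks cell percentage columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(pheno[, cols])
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vars <- pc$sdev^2
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = cumsum(vars)[seq_len(k)] / sum(vars),
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

# Build the adjustment covariate matrix from a phenotype table.
#' @keywords internal
build_covariates <- function(pheno, covariates, adjust_cells) {
  cols <- list()
  for (v in covariates) {
    if (v == "smoking_status") {
      lv <- setdiff(unique(pheno$smoking_status), "former")  # former = reference
      for (l in lv)
        cols[[paste0("smoking_", l)]] <- as.numeric(pheno$smoking_status == l)
    } else {
      if (!v %in% names(pheno))
        stop("covariate not in phenotype table: ", v, call. = FALSE)
      cols[[v]] <- pheno[[v]]
    }
  }
  out <- if (length(cols)) do.call(cbind, cols) else NULL
  if (adjust_cells) {
    pcs <- cell_count_pcs(pheno, 3L)$scores
    colnames(pcs) <- paste0("cellPC", seq_len(ncol(pcs)))
    out <- if (is.null(out)) pcs else cbind(out, pcs)
  }
  out
}

# Vectorized per-feature OLS of trait on [1, covariates, feature] via
# Frisch-Waugh residualization; algebraically identical to refitting the
# full model per feature.
#' @keywords internal
ols_scan <- function(y, features, Z) {
  n <- length(y)
  X0 <- cbind(rep(1, n), Z)
  q0 <- qr(X0)
  if (q0$rank < ncol(X0))
    stop("rank-deficient covariate design", call. = FALSE)
  ry <- qr.resid(q0, y)
  rf <- qr.resid(q0, features)            # n x m residualized features
  sxx <- colSums(rf^2)
  if (any(sxx <= 0))
    stop("feature collinear with covariates: ",
         colnames(features)[which(sxx <= 0)[1]], call. = FALSE)
  beta <- colSums(rf * ry) / sxx
  df <- n - ncol(X0) - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  data.frame(feature_id = colnames(features), estimate = beta, se = se,
             p_value = 2 * stats::pt(-abs(tval), df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
align_samples <- function(expr_samples, pheno) {
  if (!setequal(expr_samples, pheno$sample_id) ||
      length(expr_samples) != nrow(pheno)) {
    only_e <- setdiff(expr_samples, pheno$sample_id)
    only_p <- setdiff(pheno$sample_id, expr_samples)
    stop("samples mismatch between expression and phenotype; expression-only: ",
         paste(utils::head(only_e, 5), collapse = ","), "; phenotype-only: ",
         paste(utils::head(only_p, 5), collapse = ","), call. = FALSE)
  }
  pheno[match(expr_samples, pheno$sample_id), , drop = FALSE]
}

#' Genome-wide gene-trait association scan
#'
#' Per-gene OLS of the trait on the gene's expression with adjustment for
#' age, sex and pack-years (and optionally the first three cell-count
#' principal components), followed by Benjamini-Hochberg correction across
#' all genes. The per-gene p-value doubles as the gene significance (GS)
#' used in hub scoring.
#'
#' @param expr Genes x samples expression matrix.
#' @param pheno Phenotype table with `sample_id`, `fev1pp` and covariates.
#' @param adjust_cells Also adjust for the first three cell-count PCs.
#' @param covariates Covariate names (default age, sex, pack-years;
#'   `"smoking_status"` adds one-hot dummies with former as reference).
#' @param trait Trait column name (default `"fev1pp"`).
#' @return Association table sorted by p-value: feature_id, estimate, se,
#'   p_value, fdr, n_used, model_tag.
#' @export
gene_trait_scan <- function(expr, pheno, adjust_cells = FALSE,
                            covariates = c("age", "sex", "pack_years"),
                            trait = "fev1pp") {
  check_expression(expr)
  pheno <- align_samples(colnames(expr), pheno)
  Z <- build_covariates(pheno, covariates, adjust_cells)
  res <- ols_scan(pheno[[trait]], t(expr), Z)
  res$fdr <- bh_fdr(res$p_value)
  res$n_used <- ncol(expr)
  res$model_tag <- paste0("trait~x+", paste(covariates, collapse = "+"),
                          if (adjust_cells) "+cellPC1:3" else "")
  res[order(res$p_value, res$feature_id), , drop = FALSE]
}

#' Module eigengene-trait association scan
#'
#' OLS of the trait on each module eigengene with covariate adjustment and
#' Benjamini-Hochberg correction across tested modules. The grey
#' (unassigned) module is never tested.
#'
#' @param eigengenes Samples x modules eigengene matrix (or a `coexp_fit`,
#'   whose eigengenes are used).
#' @param pheno Phenotype table; sample order must match the eigengene rows
#'   via `sample_id`.
#' @param adjust_cells Adjust for the first three cell-count PCs.
#' @param covariates Base covariates; append `"smoking_status"` for the
#'   replication-cohort model.
#' @param trait Trait column name.
#' @return Association table sorted by p-value (one row per module).
#' @export
module_trait_scan <- function(eigengenes, pheno, adjust_cells = FALSE,
                              covariates = c("age", "sex", "pack_years"),
                              trait = "fev1pp") {
  if (inherits(eigengenes, "coexp_fit")) eigengenes <- eigengenes$eigengenes
  eigengenes <- eigengenes[, setdiff(colnames(eigengenes), "grey"), drop = FALSE]
  if (!ncol(eigengenes)) stop("no non-grey module to test", call. = FALSE)
  pheno <- align_samples(rownames(eigengenes), pheno)
  Z <- build_covariates(pheno, covariates, adjust_cells)
  res <- ols_scan(pheno[[trait]], eigengenes, Z)
  res$fdr <- bh_fdr(res$p_value)
  res$n_used <- nrow(eigengenes)
  res$model_tag <- paste0("trait~ME+", paste(covariates, collapse = "+"),
                          if (adjust_cells) "+cellPC1:3" else "")
  res[order(res$p_value, res$feature_id), , drop = FALSE]
}
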