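# Cell-type attribution of modules: Spearman correlation of signed module
# membership with cell-specific reference expression, permutation-tested.

#' Restrict a purified-cell reference to the network's gene universe
#'
#' @param reference Genes x cell-types numeric matrix with gene rownames.
#' @param network_genes Gene ids of the co-expression network.
#' @param min_overlap Minimum shared genes required (default 100).
#' @return The reference restricted to shared genes, ordered as they appear
#'   in `network_genes`.
#' @export
harmonize <- function(reference, network_genes, min_overlap = 100L) {
  if (is.null(rownames(reference)))
    stop("reference needs gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(reference)))
    stop("reference has duplicated gene ids", call. = FALSE)
  if (ncol(reference) < 2L)
    stop("reference needs at least 2 cell types", call. = FALSE)
  shared <- intersect(network_genes, rownames(reference))
  if (length(shared) < min_overlap)
    stop("only ", length(shared), " genes shared between reference (",
         nrow(reference), ") and network (", length(network_genes),
         "); need >= ", min_overlap, call. = FALSE)
  reference[shared, , drop = FALSE]
}

#' Cell-type specificity z-scores
#'
#' Standardizes each gene's reference expression across cell types
#' (mean 0, sd 1 along the cell-type axis, sample sd), so large positive
#' scores mark the cell types where a gene is specifically expressed.
#' Genes constant across cell types get all-zero scores and are flagged in
#' the `constant_genes` attribute.
#'
#' @param reference Genes x cell-types matrix (>= 2 cell types).
#' @return Genes x cell-types matrix of z-scores.
#' @export
specificity_scores <- function(reference) {
  if (ncol(reference) < 2L)
    stop("need at least 2 cell types", call. = FALSE)
  mu <- rowMeans(reference)
  sdv <- apply(reference, 1L, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  z <- (reference - mu) / sdv
  z[const, ] <- 0
  structure(z, constant_genes = rownames(reference)[const])
}

#' Module cell-type enrichment by permutation
#'
#' Correlates (Spearman) a module's signed membership (kME) with each cell
#' type's specificity score over the shared gene universe. Significance is
#' assessed by shuffling the gene labels of the score table
#' `n_permutations` times; the one-sided permutation p-value is
#' `(1 + #\{rho_perm >= rho_obs\}) / (n_permutations + 1)` and the largest
#' permuted rho is reported alongside (as a yardstick for the observed
#' value). Rows are sorted by decreasing observed rho.
#'
#' @param kme Named numeric vector: signed module membership of one module
#'   over the network genes.
#' @param scores Genes x cell-types specificity score matrix (from
#'   [specificity_scores()] after [harmonize()]).
#' @param n_permutations Number of label shuffles (default 10000).
#' @param seed Permutation seed.
#' @return Data frame: cell_type, rho, perm_p, best_perm_rho,
#'   n_permutations.
#' @export
module_cell_enrichment <- function(kme, scores, n_permutations = 10000L,
                                   seed = 1L) {
  shared <- intersect(names(kme), rownames(scores))
  if (length(shared) < 10L)
    stop("fewer than 10 genes shared between kME and scores", call. = FALSE)
  kme <- kme[shared]
  scores <- scores[shared, , drop = FALSE]
  g <- length(shared)

  # Spearman rho as Pearson correlation of standardized ranks; a single
  # permutation of the gene labels is shared across cell types (the score
  # table's rows are shuffled as a unit).
  rk <- standardize(rank(kme))
  rs <- apply(scores, 2L, function(s) standardize(rank(s)))
  rho_obs <- drop(crossprod(rk, rs)) / (g - 1)

  set.seed(as.integer(seed))
  ge <- matrix(NA_real_, n_permutations, ncol(scores))
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(g)
    ge[b, ] <- drop(crossprod(rk, rs[idx, , drop = FALSE])) / (g - 1)
  }
  perm_p <- (1 + colSums(ge >= rep(rho_obs, each = n_permutations))) /
    (n_permutations + 1)
  out <- data.frame(cell_type = colnames(scores), rho = rho_obs,
                    perm_p = perm_p, best_perm_rho = apply(ge, 2L, max),
                    n_permutations = as.integer(n_permutations),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$rho), , drop = FALSE]
}

#' Cell-type enrichment for every module of a fit
#'
#' Convenience wrapper running [module_cell_enrichment()] for each module
#' of a [coexp_fit()] against a purified-cell reference.
#'
#' @param fit A `coexp_fit`.
#' @param reference Genes x cell-types reference expression matrix.
#' @param modules Module colors to test (default: all non-grey modules).
#' @param module_genes_only Restrict the correlation to the module's own
#'   genes instead of all shared network genes (off by default).
#' @param n_permutations,seed Permutation settings.
#' @param min_overlap Passed to [harmonize()].
#' @return Data frame with a `module` column stacked over
#'   [module_cell_enrichment()] results, sorted by rho within module.
#' @export
cell_enrichment <- function(fit, reference, modules = NULL,
                            module_genes_only = FALSE,
                            n_permutations = 10000L, seed = 1L,
                            min_overlap = 100L) {
  stopifnot(inherits(fit, "coexp_fit"))
  ref <- harmonize(reference, fit$gene_ids, min_overlap)
  scores <- specificity_scores(ref)
  modules <- modules %||% module_names(fit$colors)
  seeds <- derive_seeds(seed, max(1L, length(modules)))
  res <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    m <- modules[i]
    kme <- fit$kme[, m]
    names(kme) <- fit$gene_ids
    if (module_genes_only) kme <- kme[fit$colors == m]
    tab <- module_cell_enrichment(kme, scores, n_permutations, seeds[i])
    tab <- cbind(module = m, tab, stringsAsFactors = FALSE)
    res[[i]] <- tab
  }
  do.call(rbind, res)
}
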