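# Module preservation between cohorts: permutation Z statistics for
# density (meanAdj, propVarExpl) and connectivity (cor.kIM, cor.cor),
# combined into Z_summary, with a random "gold" module baseline.

# Observed preservation statistics for one gene set. Adjacencies are
# rebuilt per cohort from expression, on the gene set only, with the same
# soft power as the discovery network.
#' @keywords internal
preservation_stats <- function(expr_ref, expr_test, genes, beta = 7L,
                               signed = FALSE) {
  if (length(genes) < 3L)
    stop("gene set must contain at least 3 genes", call. = FALSE)
  c_ref <- stats::cor(t(expr_ref[genes, , drop = FALSE]))
  c_test <- stats::cor(t(expr_test[genes, , drop = FALSE]))
  a_ref <- if (signed) ((1 + c_ref) / 2)^beta else abs(c_ref)^beta
  a_test <- if (signed) ((1 + c_test) / 2)^beta else abs(c_test)^beta
  ut <- upper.tri(c_ref)

  xs <- row_standardize(expr_test[genes, , drop = FALSE])
  sv <- svd(xs, nu = 0L, nv = 0L)

  c(mean_adj = mean(a_test[ut]),
    prop_var_expl = sv$d[1L]^2 / sum(sv$d^2),
    cor_kim = stats::cor(rowSums(a_ref) - 1, rowSums(a_test) - 1),
    cor_cor = stats::cor(c_ref[ut], c_test[ut]))
}

#' Observed module preservation statistics
#'
#' Density statistics evaluated in the test network: mean off-diagonal
#' intramodular adjacency (`mean_adj`) and the proportion of variance the
#' test-data eigengene explains (`prop_var_expl`). Cross-network
#' connectivity statistics: Pearson correlation of intramodular
#' connectivity vectors (`cor_kim`) and of the vectorized upper-triangle
#' correlation submatrices (`cor_cor`).
#'
#' @param expr_ref,expr_test Genes x samples expression for the reference
#'   (discovery) and test (replication) cohorts; gene sets are looked up by
#'   rowname.
#' @param genes Gene ids of the module (>= 3, present in both matrices).
#' @param beta Soft power used to rebuild adjacencies (default 7).
#' @param signed Signed adjacency mode.
#' @return Named numeric vector of the four statistics.
#' @export
observed_preservation_stats <- function(expr_ref, expr_test, genes,
                                        beta = 7L, signed = FALSE) {
  missing_ref <- setdiff(genes, rownames(expr_ref))
  missing_test <- setdiff(genes, rownames(expr_test))
  if (length(missing_ref) || length(missing_test))
    stop("gene set absent from a cohort: ",
         paste(utils::head(c(missing_ref, missing_test), 5), collapse = ","),
         call. = FALSE)
  preservation_stats(expr_ref, expr_test, genes, beta, signed)
}

#' Permutation Z-summary module preservation
#'
#' For every module (and a random "gold" module of up to `gold_size` genes
#' representing the whole network), draws `n_permutations` random gene sets
#' of matching size from the shared gene universe, recomputes the four
#' preservation statistics and standardizes the observed values:
#' `Z = (observed - permutation mean) / permutation sd`. `z_density` is the
#' median of the density Zs, `z_connectivity` the median of the
#' connectivity Zs, and `z_summary` their mean. A Z_summary above 10 is
#' conventionally read as strong preservation, below 2 as no evidence.
#'
#' @param expr_ref,expr_test Expression matrices of the two cohorts.
#' @param labels Module labels named by gene id (colors or integers;
#'   "grey"/0 = unassigned, skipped).
#' @param beta Soft power for the rebuilt adjacencies.
#' @param signed Signed adjacency mode.
#' @param n_permutations Number of permutation draws (>= 50, default 200).
#' @param seed Seed for the permutation stream.
#' @param gold_size Size cap of the random gold module (default 1000).
#' @return Object of class `module_preservation`: `summary` data frame
#'   (module, size, z_density, z_connectivity, z_summary, n_permutations,
#'   seed) and `detail` — per-module observed statistics and permutation
#'   moments.
#' @export
module_preservation <- function(expr_ref, expr_test, labels, beta = 7L,
                                signed = FALSE, n_permutations = 200L,
                                seed = 1L, gold_size = 1000L) {
  check_expression(expr_ref); check_expression(expr_test)
  if (n_permutations < 50L)
    stop("'n_permutations' must be >= 50", call. = FALSE)
  universe <- intersect(rownames(expr_ref), rownames(expr_test))
  labels <- labels[intersect(names(labels), universe)]
  mods <- module_names(labels)
  set.seed(as.integer(seed))
  sets <- lapply(stats::setNames(mods, mods),
                 function(m) names(labels)[labels == m])
  gsize <- min(gold_size, length(universe))
  sets$gold <- sample(universe, gsize)

  out <- data.frame(module = names(sets), size = lengths(sets),
                    z_density = NA_real_, z_connectivity = NA_real_,
                    z_summary = NA_real_,
                    n_permutations = as.integer(n_permutations),
                    seed = as.integer(seed),
                    row.names = NULL, stringsAsFactors = FALSE)
  detail <- vector("list", length(sets)); names(detail) <- names(sets)

  for (i in seq_along(sets)) {
    obs <- preservation_stats(expr_ref, expr_test, sets[[i]], beta, signed)
    perm <- matrix(NA_real_, n_permutations, 4L,
                   dimnames = list(NULL, names(obs)))
    for (b in seq_len(n_permutations)) {
      rs <- sample(universe, length(sets[[i]]))
      perm[b, ] <- preservation_stats(expr_ref, expr_test, rs, beta, signed)
    }
    mu <- colMeans(perm); sdv <- apply(perm, 2L, stats::sd)
    z <- (obs - mu) / sdv
    if (any(sdv == 0)) {
      warning("zero permutation sd for ", names(sets)[i],
              "; corresponding Z set to +Inf")
      z[sdv == 0] <- Inf
    }
    out$z_density[i] <- stats::median(z[c("mean_adj", "prop_var_expl")])
    out$z_connectivity[i] <- stats::median(z[c("cor_kim", "cor_cor")])
    out$z_summary[i] <- mean(c(out$z_density[i], out$z_connectivity[i]))
    detail[[i]] <- list(observed = obs, perm_mean = mu, perm_sd = sdv, z = z)
  }
  structure(list(summary = out, detail = detail, beta = beta),
            class = "module_preservation")
}

#' @export
print.module_preservation <- function(x, ...) {
  cat("Module preservation (permutation Z-summary, beta =", x$beta, ")\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot Z-summary against module size
#'
#' @param x A `module_preservation` object.
#' @param ... Passed to `plot`.
#' @export
plot.module_preservation <- function(x, ...) {
  s <- x$summary
  cols <- ifelse(s$module %in% module_colors(34), s$module, "gold")
  graphics::plot(s$size, s$z_summary, log = "x", pch = 21, bg = cols,
                 cex = 1.6, xlab = "module size",
                 ylab = expression(Z[summary]), ...)
  graphics::abline(h = c(2, 10), lty = 2, col = c("grey50", "grey20"))
  graphics::text(s$size, s$z_summary, s$module, pos = 3, cex = 0.7)
  invisible(x)
}
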