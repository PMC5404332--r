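#' Fit a weighted co-expression module model
#'
#' One-stop fitting function: Pearson correlation, soft-thresholded
#' (unsigned by default) adjacency at `beta` — or the smallest power meeting
#' the scale-free topology criterion when `beta = NULL` — topological
#' overlap, average-linkage clustering of `1 - TOM`, static tree cut with a
#' minimum module size, color naming, eigengenes and module membership.
#' Optionally merges modules whose eigengenes correlate above
#' `merge_threshold`.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param beta Soft power; `NULL` selects it via [pick_soft_threshold()].
#' @param powers,r2_cut Candidates and fit cutoff for power selection.
#' @param signed Signed network mode (default unsigned, `|cor|^beta`).
#' @param cut_height,min_module_size Tree-cut parameters
#'   (see [cut_modules()]).
#' @param merge_threshold If non-`NULL`, iteratively merge module pairs
#'   whose eigengene correlation exceeds this value (e.g. 0.75). Off by
#'   default.
#' @param keep_tom Keep the TOM matrix in the returned object (needed for
#'   [export_module_network()]; memory is quadratic in gene count).
#' @return An object of class `coexp_fit`: `labels` (integer, size-ranked),
#'   `colors` (canonical color names, "grey" = unassigned), `eigengenes`,
#'   `prop_var_explained`, `mm`/`kme` membership matrices, `dendro`,
#'   `beta`, `power_fits` (when selected), `tom` (optional) and the call
#'   parameters.
#' @seealso [module_trait_scan()], [module_preservation()],
#'   [module_cell_enrichment()], [hub_scores()], [predict.coexp_fit()]
#' @examples
#' study <- simulate_study(sim_config(n_genes = 250, module_sizes = c(60, 60),
#'                                    n_samples_discovery = 80,
#'                                    n_samples_replication = 40, seed = 2))
#' fit <- coexp_fit(study$expr_discovery, beta = 7)
#' table(fit$colors)
#' @export
coexp_fit <- function(expr, beta = 7L, powers = 1:20, r2_cut = 0.80,
                      signed = FALSE, cut_height = 0.99,
                      min_module_size = 30L, merge_threshold = NULL,
                      keep_tom = FALSE) {
  check_expression(expr, min_samples = 3L)
  cc <- correlation_matrix(expr)
  power_fits <- NULL
  qualified <- NA
  if (is.null(beta)) {
    pick <- pick_soft_threshold(cc, powers, r2_cut, signed = signed)
    beta <- pick$beta
    power_fits <- pick$fits
    qualified <- pick$qualified
    if (!qualified)
      warning("no candidate power reached r2_cut = ", r2_cut,
              "; using argmax power ", beta)
  }
  adj <- adjacency(cc, beta, signed)
  tm <- tom(adj)
  dendro <- average_linkage(1 - tm)
  labels <- cut_modules(dendro, cut_height, min_module_size)

  if (!is.null(merge_threshold) && max(labels) > 1L) {
    labels <- merge_close_modules(expr, labels, merge_threshold)
  }
  colors <- assign_colors(labels)

  if (any(labels > 0L)) {
    me <- module_eigengenes(expr, colors)
    memb <- module_membership(expr, me$eigengenes)
  } else {
    me <- list(eigengenes = matrix(numeric(0), ncol(expr), 0,
                                   dimnames = list(colnames(expr), NULL)),
               prop_var_explained = numeric(0))
    memb <- list(mm = NULL, kme = NULL)
  }

  structure(list(
    labels = labels, colors = colors,
    eigengenes = me$eigengenes, prop_var_explained = me$prop_var_explained,
    mm = memb$mm, kme = memb$kme,
    dendro = dendro, beta = as.integer(beta), signed = signed,
    power_fits = power_fits, power_qualified = qualified,
    cut_height = cut_height,
    min_module_size = as.integer(min_module_size),
    merge_threshold = merge_threshold,
    tom = if (keep_tom) tm else NULL,
    n_genes = nrow(expr), n_samples = ncol(expr),
    gene_ids = rownames(expr), sample_ids = colnames(expr)
  ), class = "coexp_fit")
}

# Iterative eigengene-similarity merging; relabels by decreasing size.
#' @keywords internal
merge_close_modules <- function(expr, labels, threshold) {
  repeat {
    if (max(labels) < 2L) return(labels)
    me <- module_eigengenes(expr, labels)$eigengenes
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[top[1], top[2]] <= threshold) break
    a <- as.integer(colnames(cc)[top[1]]); b <- as.integer(colnames(cc)[top[2]])
    labels[labels == max(a, b)] <- min(a, b)
    # renumber by decreasing size
    mods <- module_names(labels)
    new <- rep(0L, length(labels)); names(new) <- names(labels)
    for (i in seq_along(mods)) new[labels == as.integer(mods[i])] <- i
    labels <- new
  }
  labels
}

#' @export
print.coexp_fit <- function(x, ...) {
  nm <- sum(x$labels > 0L)
  mods <- module_names(x$colors)
  cat("Weighted co-expression module fit\n")
  cat(sprintf("  %d genes x %d samples, %s network, beta = %d\n",
              x$n_genes, x$n_samples, if (x$signed) "signed" else "unsigned",
              x$beta))
  cat(sprintf("  %d modules (%d genes assigned, %d grey)\n",
              length(mods), nm, x$n_genes - nm))
  if (length(mods)) {
    sizes <- table(x$colors)[mods]
    show <- utils::head(mods, 8L)
    cat("  largest: ",
        paste(sprintf("%s (%d)", show, sizes[show]), collapse = ", "),
        if (length(mods) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.coexp_fit <- function(object, ...) {
  mods <- module_names(object$colors)
  df <- data.frame(
    module = mods,
    size = as.integer(table(object$colors)[mods]),
    prop_var_explained = unname(object$prop_var_explained[mods]),
    stringsAsFactors = FALSE
  )
  structure(list(modules = df, beta = object$beta,
                 n_grey = sum(object$colors == "grey"),
                 n_genes = object$n_genes, n_samples = object$n_samples),
            class = "summary.coexp_fit")
}

#' @export
print.summary.coexp_fit <- function(x, ...) {
  cat(sprintf("Co-expression modules (beta = %d, %d genes, %d samples)\n",
              x$beta, x$n_genes, x$n_samples))
  print(x$modules, row.names = FALSE, digits = 3)
  cat(sprintf("unassigned (grey): %d genes\n", x$n_grey))
  invisible(x)
}

#' Plot a co-expression fit
#'
#' Gene dendrogram with a module color bar underneath.
#'
#' @param x A `coexp_fit`.
#' @param ... Passed to `plot.hclust`.
#' @export
plot.coexp_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$dendro, labels = FALSE, hang = -1, xlab = "", sub = "",
                 main = "Gene dendrogram (1 - TOM)", ...)
  graphics::par(mar = c(2, 4, 0.5, 1))
  ord <- x$dendro$order
  cols <- x$colors[ord]
  graphics::image(matrix(seq_along(cols), ncol = 1), col = cols, axes = FALSE)
  graphics::mtext("module", side = 2, las = 1, line = 1, cex = 0.8)
  invisible(x)
}

#' Project module eigengenes into a new cohort
#'
#' Recomputes each module's first-principal-component eigengene in
#' `newdata` using the discovery gene sets (gene membership fixed, scores
#' re-estimated), sign-aligned to discovery via positive correlation of the
#' module-membership (kME) patterns over shared genes. Modules whose gene
#' overlap with `newdata` falls below `min_overlap` are skipped with a
#' warning.
#'
#' @param object A `coexp_fit` from the discovery cohort.
#' @param newdata Genes x samples expression matrix for the new cohort.
#' @param min_overlap Minimum fraction of module genes that must be present
#'   (default 0.8).
#' @param ... Unused.
#' @return Samples x modules eigengene matrix for `newdata`.
#' @export
predict.coexp_fit <- function(object, newdata, min_overlap = 0.8, ...) {
  check_expression(newdata)
  mods <- module_names(object$colors)
  keep <- character(0)
  eg <- matrix(NA_real_, ncol(newdata), 0,
               dimnames = list(colnames(newdata), NULL))
  for (m in mods) {
    genes <- object$gene_ids[object$colors == m]
    shared <- intersect(genes, rownames(newdata))
    if (length(shared) < min_overlap * length(genes)) {
      warning("module ", m, ": only ", length(shared), "/", length(genes),
              " genes present in new data; skipped")
      next
    }
    sub <- stats::setNames(rep(m, length(shared)), shared)
    e <- module_eigengenes(newdata[shared, , drop = FALSE], sub)$eigengenes[, 1L]
    # sign-align to the discovery membership pattern via the uncentered
    # inner product: centered correlation would discard the dominant mean
    # agreement and flip on noise when membership is homogeneous
    kme_new <- drop(stats::cor(t(newdata[shared, , drop = FALSE]), e))
    if (sum(kme_new * object$kme[shared, m]) < 0) e <- -e
    eg <- cbind(eg, e)
    keep <- c(keep, m)
  }
  colnames(eg) <- keep
  eg
}
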