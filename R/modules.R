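# Module detection: average-linkage clustering on TOM dissimilarity, static
# tree cut with a minimum module size, eigengenes and module membership.

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal (typically
#'   `1 - tom(adj)`).
#' @return An object of class `hclust` (merge history, nondecreasing
#'   heights, leaf order).
#' @export
average_linkage <- function(diss) {
  check_symmetric(diss, what = "dissimilarity matrix")
  if (max(abs(diag(diss))) > 1e-12)
    stop("dissimilarity diagonal must be 0", call. = FALSE)
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Cut a gene dendrogram into modules
#'
#' Static ("tree"-method) cut at `cut_height` times the maximum merge
#' height; branches below the cut are candidate modules, candidates smaller
#' than `min_module_size` are set to unassigned (label 0, the grey module),
#' and surviving modules are renumbered by decreasing size. On a 1 - TOM
#' dissimilarity the maximum height is close to 1, so the default 0.99
#' corresponds to the conventional static cut height of 0.99: background
#' genes, whose mutual topological overlap is near zero, join the tree only
#' in its top sliver, while co-expressed branches complete well below it.
#'
#' @param dendro `hclust` tree from [average_linkage()].
#' @param cut_height Cut position as a fraction of the maximum merge
#'   height, in (0, 1]; default 0.99.
#' @param min_module_size Minimum genes per module (default 30).
#' @return Named integer vector of module labels (0 = unassigned),
#'   size-ranked so label 1 is the largest module.
#' @export
cut_modules <- function(dendro, cut_height = 0.99,
                        min_module_size = 30L) {
  stopifnot(inherits(dendro, "hclust"))
  if (cut_height <= 0 || cut_height > 1)
    stop("'cut_height' must be in (0,1]", call. = FALSE)
  if (min_module_size < 2L)
    stop("'min_module_size' must be >= 2", call. = FALSE)
  h <- cut_height * max(dendro$height)
  raw <- stats::cutree(dendro, h = h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- rep(0L, length(raw))
  names(out) <- names(raw) %||% dendro$labels
  if (!length(keep)) {
    warning("all genes unassigned: no branch reaches min_module_size")
    return(out)
  }
  # size ties broken by the lexicographically smallest member gene id so the
  # labeling is invariant to gene order
  first_gene <- vapply(keep, function(k) min(names(out)[raw == k]), character(1))
  keep <- keep[order(-sizes[as.character(keep)], first_gene)]
  for (i in seq_along(keep)) out[raw == keep[i]] <- i
  out
}

#' Module eigengenes
#'
#' Per module, gene profiles are standardized across samples and the
#' eigengene is the first right singular vector of the module block, scaled
#' to unit variance and oriented so that it correlates positively with the
#' module's mean standardized expression. The proportion of variance
#' explained is the leading singular value squared over the total.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Module labels named by gene id: integers (0 = unassigned)
#'   or color names ("grey" = unassigned). Unassigned genes are skipped.
#' @return List: `eigengenes` (samples x modules matrix, unit-variance
#'   columns) and `prop_var_explained` (named per-module vector).
#' @export
module_eigengenes <- function(expr, labels) {
  check_expression(expr)
  labels <- labels[intersect(names(labels), rownames(expr))]
  mods <- module_names(labels)
  if (!length(mods)) stop("no assigned module in 'labels'", call. = FALSE)
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  pve <- stats::setNames(numeric(length(mods)), mods)
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    xs <- row_standardize(expr[genes, , drop = FALSE])
    if (length(genes) == 1L) {
      warning("module ", mods[i], " has a single gene; returning its profile")
      eg[, i] <- drop(xs)
      pve[i] <- 1
      next
    }
    sv <- svd(xs, nu = 0L, nv = 1L)
    scores <- sv$v[, 1L]
    scores <- scores / stats::sd(scores)
    if (stats::cor(scores, colMeans(xs)) < 0) scores <- -scores
    eg[, i] <- scores
    pve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, prop_var_explained = pve)
}

# Assigned module names in size order (largest first), excluding 0/"grey".
#' @keywords internal
module_names <- function(labels) {
  lv <- labels[!(labels %in% c(0L, "0", "grey"))]
  if (!length(lv)) return(character(0))
  tab <- sort(table(lv), decreasing = TRUE)
  names(tab)
}

#' Module membership (kME)
#'
#' Correlates each gene's expression with each module eigengene. Module
#' membership MM is the absolute correlation (values in `[0,1]`); the
#' signed correlation (kME) is also returned and is the quantity used for
#' cell-type enrichment.
#'
#' @param expr Genes x samples expression matrix.
#' @param eigengenes Samples x modules eigengene matrix.
#' @return List of genes x modules matrices `mm` (absolute) and `kme`
#'   (signed).
#' @export
module_membership <- function(expr, eigengenes) {
  check_expression(expr)
  if (nrow(eigengenes) != ncol(expr))
    stop("eigengenes and expression must share samples", call. = FALSE)
  sdv <- apply(expr, 1L, stats::sd)
  if (any(sdv == 0))
    stop("module membership undefined for zero-variance gene: ",
         rownames(expr)[which(sdv == 0)[1]], call. = FALSE)
  kme <- stats::cor(t(expr), eigengenes)
  list(mm = abs(kme), kme = kme)
}
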