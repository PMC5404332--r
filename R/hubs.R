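# Hub genes: sum of module-membership and gene-significance ranks; export
# of hub-centered subnetworks as edge lists / GraphML.

#' Rank module hub genes
#'
#' Hubs are module genes with the smallest sum of two ranks: module
#' membership ranked descending (1 = highest MM) and trait-association
#' p-value ranked ascending (1 = most significant). Ties within either
#' ranking use average ranks; ties on the sum are broken by smaller
#' p-value, then gene id.
#'
#' @param module_genes Gene ids of one module.
#' @param mm Module membership values in `[0,1]`, named by gene id (may
#'   cover more genes than the module).
#' @param gs_p Gene-significance p-values in (0,1], named by gene id.
#' @return Data frame sorted by hub rank: gene_id, mm, gs_p, rank_mm,
#'   rank_gs, rank_sum, hub_rank.
#' @export
hub_scores <- function(module_genes, mm, gs_p) {
  mm <- mm[module_genes]; gs_p <- gs_p[module_genes]
  if (anyNA(mm) || anyNA(gs_p))
    stop("missing MM or gene-significance value for: ",
         paste(utils::head(module_genes[is.na(mm) | is.na(gs_p)], 5),
               collapse = ","), call. = FALSE)
  rank_mm <- rank(-mm)
  rank_gs <- rank(gs_p)
  rank_sum <- rank_mm + rank_gs
  ord <- order(rank_sum, gs_p, module_genes)
  data.frame(gene_id = module_genes, mm = unname(mm), gs_p = unname(gs_p),
             rank_mm = unname(rank_mm), rank_gs = unname(rank_gs),
             rank_sum = unname(rank_sum),
             hub_rank = match(seq_along(ord), ord),
             row.names = NULL, stringsAsFactors = FALSE)[ord, , drop = FALSE]
}

#' Export a module's significant-gene subnetwork
#'
#' Selects up to `top_n` module genes whose trait-association FDR passes
#' `fdr_cut`, ranked by significance, and emits the complete weighted graph
#' among them: edge weight = topological overlap, node significance =
#' -log10 p (for "node size proportional to significance" rendering).
#'
#' @param tom TOM matrix covering the module genes (e.g. from
#'   `coexp_fit(..., keep_tom = TRUE)$tom`).
#' @param module_genes Gene ids of the module.
#' @param gs_p Named p-values for trait association.
#' @param gs_fdr Named BH-adjusted values; defaults to `bh_fdr` over
#'   `gs_p` if missing.
#' @param top_n Maximum nodes (default 50).
#' @param fdr_cut FDR threshold for inclusion (default 0.05).
#' @return List: `nodes` (gene_id, gs_p, gs_fdr, neg_log10_p) and `edges`
#'   (gene_a, gene_b, tom_weight), both deterministically ordered.
#' @export
export_module_network <- function(tom, module_genes, gs_p, gs_fdr = NULL,
                                  top_n = 50L, fdr_cut = 0.05) {
  if (is.null(gs_fdr)) gs_fdr <- stats::setNames(bh_fdr(gs_p), names(gs_p))
  missing <- setdiff(module_genes, rownames(tom))
  if (length(missing))
    stop("TOM lacks module genes: ",
         paste(utils::head(missing, 5), collapse = ","), call. = FALSE)
  p <- gs_p[module_genes]; f <- gs_fdr[module_genes]
  pass <- module_genes[!is.na(f) & f < fdr_cut]
  if (!length(pass)) {
    warning("no module gene passes fdr_cut = ", fdr_cut)
    return(list(nodes = data.frame(gene_id = character(0), gs_p = numeric(0),
                                   gs_fdr = numeric(0),
                                   neg_log10_p = numeric(0)),
                edges = data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   tom_weight = numeric(0))))
  }
  pass <- pass[order(p[pass], pass)]
  pass <- utils::head(pass, top_n)
  nodes <- data.frame(gene_id = pass, gs_p = unname(p[pass]),
                      gs_fdr = unname(f[pass]),
                      neg_log10_p = -log10(unname(p[pass])),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (length(pass) < 2L) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        tom_weight = numeric(0))
  } else {
    idx <- utils::combn(length(pass), 2L)
    edges <- data.frame(gene_a = pass[idx[1L, ]], gene_b = pass[idx[2L, ]],
                        tom_weight = tom[cbind(pass[idx[1L, ]],
                                               pass[idx[2L, ]])],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Write an exported module network as GraphML
#'
#' @param network List from [export_module_network()].
#' @param path Output file.
#' @param module Optional module name stored as a node attribute.
#' @param mm Optional named MM vector stored as a node attribute.
#' @return `path`, invisibly.
#' @export
write_module_graphml <- function(network, path, module = NA_character_,
                                 mm = NULL) {
  nodes <- network$nodes
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = nodes$gene_id, module = module,
                          mm = if (is.null(mm)) NA_real_ else
                            unname(mm[nodes$gene_id]),
                          gs_p = nodes$gs_p,
                          neg_log10_p = nodes$neg_log10_p,
                          stringsAsFactors = FALSE))
  if (igraph::ecount(g))
    igraph::E(g)$weight <- network$edges$tom_weight
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
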