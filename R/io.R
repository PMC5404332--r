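# Tab-separated readers/writers. Every file written by the pipeline starts
# with a '# coexpmod config <hash>' comment line; readers skip '#' lines.

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated, first column `gene_id`, header row of sample ids.
#' Duplicate gene ids, missing cells and non-numeric cells are rejected
#' with coordinates.
#'
#' @param path File path.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (names(df)[1] != "gene_id")
    stop("expression file must have 'gene_id' as first column, got '",
         names(df)[1], "' (", path, ")", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or non-numeric cell in ", path, " at gene '",
         ids[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'",
         call. = FALSE)
  rownames(num) <- ids
  num
}

#' Write a gene-by-sample expression matrix
#'
#' @param expr Numeric matrix with dimnames.
#' @param path Output path.
#' @param header Optional comment line(s) written before the table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  # %.17g keeps full double precision so write -> read round-trips exactly
  body <- matrix(sprintf("%.17g", expr), nrow(expr))
  writeLines(paste(rownames(expr), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with columns sample_id, fev1pp, age, sex, pack_years,
#' smoking_status and the five cell percentages.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "fev1pp", "age", "sex", "pack_years",
            "smoking_status", "neut_pct", "lymph_pct", "mono_pct",
            "eos_pct", "baso_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in ", path, ": ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  df
}

#' @keywords internal
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-cell-type reference expression table
#'
#' @param path Tab-separated file, first column `gene_id`, one column per
#'   cell type.
#' @return Numeric genes x cell-types matrix.
#' @export
read_cell_reference <- function(path) {
  m <- read_expression(path)
  if (ncol(m) < 2L)
    stop("cell reference needs >= 2 cell types (", path, ")", call. = FALSE)
  m
}
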