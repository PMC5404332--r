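`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_expression <- function(expr, min_samples = 1L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))])[1:3], collapse = ", "),
         call. = FALSE)
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  if (ncol(expr) < min_samples)
    stop("need at least ", min_samples, " samples, got ", ncol(expr), call. = FALSE)
  invisible(expr)
}

#' @keywords internal
check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " is not symmetric", call. = FALSE)
  invisible(m)
}

# Deterministic sub-seeds: one master seed fans out to independent streams,
# all kept below 2^31 so set.seed() accepts them on any platform.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant vector", call. = FALSE)
  (x - mean(x)) / s
}

# Row-standardize a genes x samples block; zero-variance genes are an error
# (callers validate earlier with a gene name).
#' @keywords internal
row_standardize <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance gene: ", rownames(x)[which(sdv == 0)[1]], call. = FALSE)
  (x - mu) / sdv
}
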