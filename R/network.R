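# Weighted network construction: correlation -> soft-thresholded adjacency
# -> topological overlap, with scale-free topology based power selection.

#' Gene-gene Pearson correlation matrix
#'
#' @param expr Numeric genes x samples matrix with dimnames; at least three
#'   samples, no zero-variance gene.
#' @return Symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
correlation_matrix <- function(expr) {
  check_expression(expr, min_samples = 3L)
  sdv <- apply(expr, 1L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance gene: ", rownames(expr)[which(sdv == 0)[1]], call. = FALSE)
  cc <- stats::cor(t(expr))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Soft-thresholded adjacency
#'
#' Unsigned network (default): `a_ij = |cor_ij|^beta`. Signed network:
#' `a_ij = ((1 + cor_ij)/2)^beta`.
#'
#' @param cor Correlation matrix from [correlation_matrix()].
#' @param beta Soft-thresholding power, positive integer.
#' @param signed Use the signed transformation.
#' @return Adjacency matrix in `[0,1]`, unit diagonal, with attributes
#'   `beta` and `signed`.
#' @export
adjacency <- function(cor, beta = 7L, signed = FALSE) {
  check_symmetric(cor, what = "correlation matrix")
  if (length(beta) != 1L || beta < 1 || beta != round(beta))
    stop("'beta' must be a positive integer", call. = FALSE)
  a <- if (signed) ((1 + cor) / 2)^beta else abs(cor)^beta
  diag(a) <- 1
  structure(a, beta = as.integer(beta), signed = signed)
}

#' Scale-free topology fit of a network's degree distribution
#'
#' Computes connectivity `k_i = sum_{j != i} a_ij`, bins it into `n_bins`
#' equal-width bins, and regresses `log10 p(k)` on `log10 mean(k)` over
#' nonempty bins. The fit index is R-squared signed by minus the slope sign,
#' so a positive value indicates the decreasing degree distribution expected
#' under approximate scale-free topology.
#'
#' @param adj Adjacency matrix (unit diagonal).
#' @param n_bins Number of equal-width connectivity bins (>= 5).
#' @return List: `power` (the adjacency's beta, if recorded), `r_squared`,
#'   `mean_connectivity`, `slope`, and the per-bin `fit_table`.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  check_symmetric(adj, what = "adjacency matrix")
  if (n_bins < 5L) stop("'n_bins' must be >= 5", call. = FALSE)
  k <- colSums(adj) - diag(adj)
  if (diff(range(k)) == 0)
    stop("scale-free fit undefined: constant connectivity", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  keep <- cnt > 0L
  if (sum(keep) < 3L)
    stop("scale-free fit undefined: fewer than 3 nonempty connectivity bins",
         call. = FALSE)
  mean_k <- vapply(which(keep), function(b) mean(k[as.integer(bin) == b]), numeric(1))
  p_k <- cnt[keep] / length(k)
  if (any(mean_k <= 0))
    stop("scale-free fit undefined: nonpositive mean connectivity in a bin",
         call. = FALSE)
  fit <- stats::lm(log10(p_k) ~ log10(mean_k))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2]]
  list(power = attr(adj, "beta"),
       r_squared = -sign(slope) * r2,
       mean_connectivity = mean(k),
       slope = slope,
       fit_table = data.frame(mean_k = mean_k, p_k = p_k, count = cnt[keep]))
}

#' Choose the soft-thresholding power by scale-free topology criterion
#'
#' Returns the smallest candidate power whose signed fit index reaches
#' `r2_cut`; if none qualifies, the power with the maximal fit is returned
#' and flagged.
#'
#' @param cor Correlation matrix.
#' @param powers Candidate powers (default 1..20).
#' @param r2_cut Signed R-squared threshold (default 0.80).
#' @param n_bins Bins for [scale_free_fit()].
#' @param signed Signed network mode.
#' @return List: `beta` (chosen power), `qualified` (did any power reach the
#'   cut), and `fits` — a data frame with power, r_squared and
#'   mean_connectivity for every candidate.
#' @export
pick_soft_threshold <- function(cor, powers = 1:20, r2_cut = 0.80,
                                n_bins = 10L, signed = FALSE) {
  if (!length(powers)) stop("'powers' must be nonempty", call. = FALSE)
  fits <- data.frame(power = powers, r_squared = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    sf <- tryCatch(scale_free_fit(adjacency(cor, powers[i], signed), n_bins),
                   error = function(e) NULL)
    if (!is.null(sf)) {
      fits$r_squared[i] <- sf$r_squared
      fits$mean_connectivity[i] <- sf$mean_connectivity
    }
  }
  ok <- which(!is.na(fits$r_squared) & fits$r_squared >= r2_cut)
  if (length(ok)) {
    list(beta = as.integer(powers[ok[1]]), qualified = TRUE, fits = fits)
  } else {
    best <- which.max(fits$r_squared)
    list(beta = as.integer(powers[best]), qualified = FALSE, fits = fits)
  }
}

#' Topological overlap matrix
#'
#' For adjacency `a` with unit diagonal, off-diagonal overlap is
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj Symmetric adjacency in `[0,1]` with unit diagonal.
#' @return TOM matrix in `[0,1]`, same dimnames.
#' @export
tom <- function(adj) {
  check_symmetric(adj, what = "adjacency matrix")
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12)
    stop("adjacency entries must lie in [0,1]", call. = FALSE)
  if (max(abs(diag(adj) - 1)) > 1e-12)
    stop("adjacency diagonal must be 1", call. = FALSE)
  a <- unclass(adj)
  n <- nrow(a)
  k <- colSums(a) - 1
  # (A %*% A)_ij counts u = i and u = j; both contribute a_ij (diag = 1).
  l <- crossprod(a)
  l <- l - 2 * a        # off-diagonal: sum over u != i,j
  kmin <- pmin(matrix(k, n, n), matrix(k, n, n, byrow = TRUE))
  tm <- (l + a) / (kmin + 1 - a)
  tm[tm < 0] <- 0
  tm[tm > 1] <- 1
  diag(tm) <- 1
  tm <- (tm + t(tm)) / 2
  dimnames(tm) <- dimnames(a)
  tm
}
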