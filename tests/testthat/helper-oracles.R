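# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (loops, closed forms) and share no code with
# the package internals they verify.

# Pairwise Pearson correlation, two genes at a time.
oracle_cor <- function(expr) {
  n <- nrow(expr)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(expr), rownames(expr))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    x <- expr[i, ]; y <- expr[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    out[i, j] <- out[j, i] <- r
  }
  out
}

# Triple-loop topological overlap.
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- diag(1, n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- out[j, i] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# Naive quadratic-time UPGMA: returns sorted merge heights.
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dm <- d
  heights <- numeric(0)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(1, 2); bd <- Inf
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      dij <- mean(dm[active[[i]], active[[j]]])
      if (dij < bd) { bd <- dij; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# Binned log-log scale-free regression.
oracle_scale_free <- function(a, n_bins = 10) {
  k <- sapply(seq_len(nrow(a)), function(i) sum(a[i, -i]))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  mk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  keep <- !is.na(mk) & pk > 0
  fit <- lm(log10(pk[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

# OLS slope/SE/p for y ~ [1, x, covs] from the normal equations.
oracle_ols <- function(y, x, covs = NULL) {
  X <- cbind(1, x, covs)
  xtx <- solve(t(X) %*% X)
  b <- xtx %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * diag(xtx))[2]
  t <- b[2] / se
  list(estimate = b[2], se = se,
       p = 2 * pt(-abs(t), length(y) - ncol(X)))
}

# Step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in seq.int(m - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  si <- sum(choose(tab, 2)); sr <- sum(choose(rs, 2)); sc <- sum(choose(cs, 2))
  ei <- sr * sc / choose(n, 2)
  (si - ei) / ((sr + sc) / 2 - ei)
}

# Small random symmetric adjacency with unit diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Small expression fixture.
random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# Quick small simulated study shared across tests.
small_study <- function(seed = 42, ...) {
  simulate_study(sim_config(n_genes = 400, module_sizes = c(50, 50, 40),
                            n_samples_discovery = 100,
                            n_samples_replication = 100,
                            trait_effects = c(-0.4, 0.35, 0),
                            cell_driven_modules = c("1" = "neutrophil"),
                            seed = seed, ...))
}
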