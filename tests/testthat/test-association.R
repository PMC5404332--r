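test_that("linear association matches the normal-equations oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 60
    covs <- cbind(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5),
                  py = rnorm(n, 40, 20))
    x <- rnorm(n)
    y <- 50 - 3 * x + 0.2 * covs[, 1] + rnorm(n, sd = 8)
    got <- linear_association(y, x, covs)
    want <- oracle_ols(y, x, covs)
    expect_equal(got$estimate, unname(want$estimate), tolerance = 1e-10)
    expect_equal(got$se, unname(want$se), tolerance = 1e-10)
    expect_equal(got$p_value, unname(want$p), tolerance = 1e-10)
    expect_equal(got$n_used, n)
  }
  # exact fit
  x <- 1:10
  ex <- linear_association(2 * x, x)
  expect_equal(ex$estimate, 2, tolerance = 1e-12)
  expect_lt(ex$p_value, 1e-12)
  # textbook 5 points: slope and SE by hand
  hx <- c(1, 2, 3, 4, 5); hy <- c(2, 3, 5, 4, 6)
  hand <- oracle_ols(hy, hx)
  got2 <- linear_association(hy, hx)
  expect_equal(got2$estimate, unname(hand$estimate), tolerance = 1e-12)
  expect_equal(got2$se, unname(hand$se), tolerance = 1e-12)
  # collinear design errors
  expect_error(linear_association(rnorm(20), x = rep(1, 20) * 2,
                                  covariates = cbind(z = rep(3, 20))),
               "collinear|rank")
})

test_that("OLS p-values are calibrated under the null", {
  set.seed(99)
  p <- replicate(400, {
    n <- 100
    linear_association(rnorm(n), rnorm(n),
                       cbind(a = rnorm(n), b = rnorm(n)))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("results are invariant to covariate column order", {
  set.seed(5)
  n <- 50
  covs <- cbind(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
  x <- rnorm(n); y <- 2 + x + covs %*% c(1, -1, 0.5) + rnorm(n)
  r1 <- linear_association(y, x, covs)
  r2 <- linear_association(y, x, covs[, c(3, 1, 2)])
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("BH adjustment equals the step-up oracle and its closed forms", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  for (seed in 1:4) {
    set.seed(seed)
    p <- runif(1000)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # order invariance
  set.seed(9); p <- runif(200)
  o <- sample(200)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 0)), "0,1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0,1")
})

test_that("cell-count PCs capture compositional structure", {
  study <- small_study(seed = 11)
  pcs <- cell_count_pcs(study$pheno_discovery, 3)
  expect_equal(dim(pcs$scores), c(100L, 3L))
  # Dirichlet fractions: first 3 PCs explain > 95% of variance
  expect_gt(pcs$variance_explained[3], 0.95)
  # percentages sum to 100 -> the 5th PC carries no variance
  full <- cell_count_pcs(study$pheno_discovery, 5)
  expect_lt(1 - full$variance_explained[4], 1e-9)
  # deterministic sign convention: largest |loading| positive
  for (j in 1:3)
    expect_gt(pcs$loadings[which.max(abs(pcs$loadings[, j])), j], 0)
  expect_error(cell_count_pcs(data.frame(neut_pct = 1)), "lymph_pct")
})

test_that("gene scan finds planted trait genes and validates alignment", {
  study <- simulate_study(sim_config(
    n_genes = 300, module_sizes = c(40, 40), trait_effects = c(0.8, 0),
    cell_driven_modules = NULL, n_samples_discovery = 150,
    n_samples_replication = 20, seed = 13))
  scan <- gene_trait_scan(study$expr_discovery, study$pheno_discovery)
  expect_equal(nrow(scan), 300L)
  expect_true(!is.unsorted(scan$p_value))
  top <- scan$feature_id[1]
  expect_equal(unname(study$true_labels[top]), 1L)
  # scan agrees with single-gene refits
  g <- scan$feature_id[5]
  single <- linear_association(
    study$pheno_discovery$fev1pp, study$expr_discovery[g, ],
    as.matrix(study$pheno_discovery[, c("age", "sex", "pack_years")]))
  expect_equal(scan$estimate[5], single$estimate, tolerance = 1e-10)
  expect_equal(scan$se[5], single$se, tolerance = 1e-10)
  expect_equal(scan$p_value[5], single$p_value, tolerance = 1e-10)

  bad <- study$pheno_discovery
  bad$sample_id[1] <- "nope"
  expect_error(gene_trait_scan(study$expr_discovery, bad), "mismatch")
})

test_that("module scan excludes grey and matches planted effect signs", {
  study <- small_study(seed = 14)
  labs <- setNames(ifelse(study$true_labels > 0,
                          paste0("m", study$true_labels), "grey"),
                   names(study$true_labels))
  eg <- module_eigengenes(study$expr_discovery, labs)$eigengenes
  eg <- cbind(eg, grey = rnorm(nrow(eg)))
  scan <- module_trait_scan(eg, study$pheno_discovery)
  expect_false("grey" %in% scan$feature_id)
  # planted effects: module 1 beta < 0, module 2 beta > 0
  expect_lt(scan$estimate[scan$feature_id == "m1"], 0)
  expect_gt(scan$estimate[scan$feature_id == "m2"], 0)
  expect_equal(scan$feature_id[scan$p_value == min(scan$p_value)],
               scan$feature_id[1])
})

test_that("eigengene projection is idempotent on an identical cohort", {
  study <- small_study(seed = 15)
  fit <- coexp_fit(study$expr_discovery, beta = 7)
  eg_same <- predict(fit, study$expr_discovery)
  for (m in colnames(eg_same))
    expect_equal(abs(cor(eg_same[, m], fit$eigengenes[, m])), 1,
                 tolerance = 1e-8)
  # low overlap is skipped with a warning
  keep <- fit$gene_ids[fit$colors != names(sort(table(fit$colors[fit$colors != "grey"]),
                                                decreasing = TRUE))[1]]
  expect_warning(predict(fit, study$expr_replication[keep, ]), "skipped")
})

test_that("smoking status enters as one-hot with former as reference", {
  study <- small_study(seed = 16)
  eg <- coexp_fit(study$expr_discovery, beta = 7)$eigengenes
  eg_rep <- predict(coexp_fit(study$expr_discovery, beta = 7),
                    study$expr_replication)
  scan <- module_trait_scan(eg_rep, study$pheno_replication,
                            covariates = c("age", "sex", "pack_years",
                                           "smoking_status"))
  expect_true(all(grepl("smoking_status", scan$model_tag)))
  expect_equal(nrow(scan), ncol(eg_rep))
})
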