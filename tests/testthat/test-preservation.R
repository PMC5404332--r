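test_that("observed statistics are exact on a hand-computed 5-gene toy", {
  set.seed(17)
  expr_ref <- random_expression(5, 30, seed = 18)
  expr_test <- random_expression(5, 30, seed = 19)
  genes <- rownames(expr_ref)
  stats <- observed_preservation_stats(expr_ref, expr_test, genes, beta = 3)

  c_ref <- cor(t(expr_ref)); c_test <- cor(t(expr_test))
  a_ref <- abs(c_ref)^3; a_test <- abs(c_test)^3
  ut <- upper.tri(c_test)
  expect_equal(unname(stats["mean_adj"]), mean(a_test[ut]), tolerance = 1e-12)
  expect_equal(unname(stats["cor_cor"]), cor(c_ref[ut], c_test[ut]),
               tolerance = 1e-12)
  kim_r <- rowSums(a_ref) - 1; kim_t <- rowSums(a_test) - 1
  expect_equal(unname(stats["cor_kim"]), cor(kim_r, kim_t), tolerance = 1e-12)
  xs <- t(scale(t(expr_test)))
  ev <- eigen(tcrossprod(xs))$values
  expect_equal(unname(stats["prop_var_expl"]), ev[1] / sum(ev),
               tolerance = 1e-10)
  expect_error(observed_preservation_stats(expr_ref, expr_test,
                                           genes[1:2]), "3 genes")
})

test_that("self-comparison gives perfect connectivity preservation", {
  study <- small_study(seed = 20)
  genes <- names(study$true_labels)[study$true_labels == 1]
  stats <- observed_preservation_stats(study$expr_discovery,
                                       study$expr_discovery, genes, beta = 7)
  expect_equal(unname(stats["cor_kim"]), 1, tolerance = 1e-12)
  expect_equal(unname(stats["cor_cor"]), 1, tolerance = 1e-12)
})

test_that("planted modules preserve strongly, random sets do not", {
  study <- simulate_study(sim_config(
    n_genes = 800, module_sizes = rep(50, 3), loadings = 0.8,
    trait_effects = 0, cell_driven_modules = NULL,
    n_samples_discovery = 150, n_samples_replication = 150, seed = 23))
  labels <- setNames(ifelse(study$true_labels > 0,
                            paste0("m", study$true_labels), "grey"),
                     names(study$true_labels))
  pres <- module_preservation(study$expr_discovery, study$expr_replication,
                              labels, beta = 7, n_permutations = 80,
                              seed = 3, gold_size = 300)
  s <- pres$summary
  planted <- s[s$module != "gold", ]
  expect_true(all(planted$z_summary > 10))
  expect_true(all(planted$z_summary > s$z_summary[s$module == "gold"]))
  expect_equal(s$z_summary, (s$z_density + s$z_connectivity) / 2,
               tolerance = 1e-12)

  # a size-matched uniformly random gene set shows no preservation
  set.seed(99)
  rnd <- sample(names(study$true_labels), 50)
  fake <- setNames(rep("fake", 50), rnd)
  pres0 <- module_preservation(study$expr_discovery, study$expr_replication,
                               fake, beta = 7, n_permutations = 80,
                               seed = 4, gold_size = 300)
  expect_lt(abs(pres0$summary$z_summary[pres0$summary$module == "fake"]), 2)
})

test_that("preservation is deterministic under a fixed seed and invariant to order", {
  study <- small_study(seed = 24)
  labels <- setNames(ifelse(study$true_labels > 0,
                            paste0("m", study$true_labels), "grey"),
                     names(study$true_labels))
  p1 <- module_preservation(study$expr_discovery, study$expr_replication,
                            labels, n_permutations = 50, seed = 7,
                            gold_size = 100)
  p2 <- module_preservation(study$expr_discovery, study$expr_replication,
                            labels, n_permutations = 50, seed = 7,
                            gold_size = 100)
  expect_identical(p1$summary, p2$summary)

  # permuting sample order within a cohort leaves Z unchanged (correlations
  # are sample-order invariant; the permutation stream is seed-driven)
  set.seed(1)
  sp <- sample(ncol(study$expr_discovery))
  p3 <- module_preservation(study$expr_discovery[, sp],
                            study$expr_replication, labels,
                            n_permutations = 50, seed = 7, gold_size = 100)
  expect_equal(p1$summary$z_summary, p3$summary$z_summary, tolerance = 1e-8)
})

test_that("tighter modules preserve more strongly on the density axis", {
  # with a module-level loading, within-module connectivity differences are
  # pure noise, so the connectivity Zs carry no lambda signal; density does
  zs <- sapply(c(0.4, 0.6, 0.9), function(lam) {
    med <- sapply(1:3, function(s) {
      study <- simulate_study(sim_config(
        n_genes = 300, module_sizes = 50, loadings = lam, trait_effects = 0,
        cell_driven_modules = NULL, n_samples_discovery = 120,
        n_samples_replication = 120, seed = 31 + s))
      labels <- setNames(ifelse(study$true_labels > 0, "m1", "grey"),
                         names(study$true_labels))
      module_preservation(study$expr_discovery, study$expr_replication,
                          labels, n_permutations = 60, seed = 9,
                          gold_size = 100)$summary$z_density[1]
    })
    median(med)
  })
  expect_true(all(diff(zs) > 0))
})
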