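test_that("average linkage reproduces naive UPGMA merge heights", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- matrix(runif(144), 12); d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("g", 1:12), paste0("g", 1:12))
    h <- average_linkage(d)
    expect_equal(sort(h$height), oracle_upgma_heights(d), tolerance = 1e-12)
    expect_equal(length(h$height), 11L)
    expect_true(all(diff(h$height) >= -1e-12))
  }
  d2 <- matrix(runif(16), 4); diag(d2) <- 0
  expect_error(average_linkage(d2), "symmetric")
})

test_that("well-separated pairs merge first", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  dimnames(d) <- list(letters[1:4], letters[1:4])
  h <- average_linkage(d)
  expect_equal(h$height[1:2], c(0.1, 0.2))
  expect_setequal(abs(h$merge[1, ]), c(1, 2))
  expect_setequal(abs(h$merge[2, ]), c(3, 4))
})

test_that("static cut recovers a perfect planted cluster and respects min size", {
  set.seed(10)
  base <- rnorm(50)
  expr <- rbind(
    matrix(rep(base, 40), 40, byrow = TRUE) + matrix(rnorm(40 * 50, sd = 0.01), 40),
    matrix(rnorm(60 * 50), 60))
  dimnames(expr) <- list(paste0("g", 1:100), paste0("s", 1:50))
  tm <- tom(adjacency(correlation_matrix(expr), 7))
  dendro <- average_linkage(1 - tm)
  # the duplicates merge at height ~0, background only near 1; a deep cut
  # keeps chance-correlated background genes out of the module
  labels <- cut_modules(dendro, cut_height = 0.9, min_module_size = 30)
  expect_equal(sum(labels == 1), 40L)
  expect_setequal(names(labels)[labels == 1], paste0("g", 1:40))
  # min size larger than every branch leaves everything grey
  expect_warning(l2 <- cut_modules(dendro, min_module_size = 90L),
                 "unassigned")
  expect_true(all(l2 == 0))
})

test_that("module labels are permutation-invariant in gene order", {
  study <- small_study(seed = 21)
  expr <- study$expr_discovery
  fit1 <- coexp_fit(expr, beta = 7)
  set.seed(1)
  perm <- sample(nrow(expr))
  fit2 <- coexp_fit(expr[perm, ], beta = 7)
  expect_equal(fit2$colors[rownames(expr)], fit1$colors[rownames(expr)])
})

test_that("color naming follows the size-ranked canonical sequence", {
  labels <- setNames(c(rep(2L, 5), rep(1L, 3), rep(3L, 7), 0L, 0L),
                     paste0("g", 1:17))
  cols <- assign_colors(labels)
  expect_equal(unname(cols[labels == 3]), rep("turquoise", 7))  # largest
  expect_equal(unname(cols[labels == 2]), rep("blue", 5))
  expect_equal(unname(cols[labels == 1]), rep("brown", 3))
  expect_equal(unname(cols[labels == 0]), rep("grey", 2))
  expect_equal(module_colors(3), c("turquoise", "blue", "brown"))
  expect_equal(module_colors(36)[35:36], c("module_35", "module_36"))
})

test_that("eigengenes: identical profiles, noise modules, planted factors", {
  # identical standardized profiles -> eigengene equals the profile, pve = 1
  set.seed(2)
  prof <- rnorm(40)
  expr <- matrix(rep(prof, 10), 10, byrow = TRUE) +
    matrix(rnorm(400, sd = 1e-8), 10)
  dimnames(expr) <- list(paste0("g", 1:10), paste0("s", 1:40))
  me <- module_eigengenes(expr, setNames(rep(1L, 10), rownames(expr)))
  expect_equal(me$prop_var_explained[["1"]], 1, tolerance = 1e-6)
  expect_gt(cor(me$eigengenes[, 1], prof), 0.999)
  expect_equal(sd(me$eigengenes[, 1]), 1, tolerance = 1e-12)

  # independent noise genes explain little variance
  noise <- random_expression(10, 500, seed = 3)
  me2 <- module_eigengenes(noise, setNames(rep(1L, 10), rownames(noise)))
  expect_lt(me2$prop_var_explained[["1"]], 0.5)

  # planted module factor is recovered almost exactly
  study <- small_study(seed = 4)
  labs <- setNames(ifelse(study$true_labels > 0,
                          paste0("m", study$true_labels), "grey"),
                   names(study$true_labels))
  me3 <- module_eigengenes(study$expr_discovery, labs)
  for (k in 1:3)
    expect_gt(abs(cor(me3$eigengenes[, paste0("m", k)],
                      study$factors_discovery[, k])), 0.95)
})

test_that("eigengene sign makes module genes' mean signed kME positive", {
  study <- small_study(seed = 6)
  labs <- setNames(ifelse(study$true_labels > 0,
                          paste0("m", study$true_labels), "grey"),
                   names(study$true_labels))
  me <- module_eigengenes(study$expr_discovery, labs)
  memb <- module_membership(study$expr_discovery, me$eigengenes)
  for (k in paste0("m", 1:3))
    expect_gt(mean(memb$kme[names(labs)[labs == k], k]), 0)
})

test_that("module membership is the absolute eigengene correlation", {
  study <- small_study(seed = 7)
  fit <- coexp_fit(study$expr_discovery, beta = 7)
  eg <- fit$eigengenes[, 1]
  expr <- rbind(study$expr_discovery,
                same = eg * 3 + 1,       # affine copy of the eigengene
                anti = -eg)
  memb <- module_membership(expr, fit$eigengenes)
  expect_equal(memb$mm["same", 1], 1, tolerance = 1e-12)
  expect_equal(memb$mm["anti", 1], 1, tolerance = 1e-12)
  expect_equal(memb$kme["anti", 1], -1, tolerance = 1e-12)
  expect_true(all(memb$mm >= 0 & memb$mm <= 1))

  # random genes against a 1000-sample eigengene have tiny MM
  set.seed(8)
  long <- matrix(rnorm(20 * 1000), 20,
                 dimnames = list(paste0("r", 1:20), paste0("s", 1:1000)))
  eg2 <- matrix(rnorm(1000), dimnames = list(colnames(long), "m"))
  memb2 <- module_membership(long, eg2)
  expect_true(mean(memb2$mm < 0.1) > 0.95)
})

test_that("optional eigengene merging collapses near-duplicate modules", {
  set.seed(30)
  f <- rnorm(80)
  expr <- rbind(
    0.9 * matrix(f, 40, 80, byrow = TRUE) + 0.3 * matrix(rnorm(3200), 40),
    0.9 * matrix(f, 40, 80, byrow = TRUE) + 0.3 * matrix(rnorm(3200), 40),
    matrix(rnorm(40 * 80), 40))
  dimnames(expr) <- list(paste0("g", 1:120), paste0("s", 1:80))
  plain <- coexp_fit(expr, beta = 7, min_module_size = 20)
  merged <- coexp_fit(expr, beta = 7, min_module_size = 20,
                      merge_threshold = 0.75)
  expect_lte(length(setdiff(unique(merged$colors), "grey")),
             length(setdiff(unique(plain$colors), "grey")))
})
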