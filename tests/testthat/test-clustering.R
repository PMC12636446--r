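# Transform chain, correlation distance, Ward agglomeration (with a
# brute-force oracle), cluster means and representative genes.

test_that("bin_and_transform applies the stated chain", {
  co <- small_cohort()
  prof <- bin_and_transform(co$rpm, co$samples$age_since_L4, first_bin_norm = FALSE)
  # z-scored rows: mean 0, sd 1
  expect_equal(unname(rowMeans(prof$values)), rep(0, nrow(prof$values)), tolerance = 1e-12)
  expect_equal(unname(apply(prof$values, 1, sd)), rep(1, nrow(prof$values)), tolerance = 1e-12)
  # re-z-scoring changes nothing (idempotence)
  again <- t(scale(t(prof$values)))
  attributes(again) <- attributes(again)["dim"]
  expect_equal(again, unname(prof$values), tolerance = 1e-12)
  # first-bin normalization zeroes column 1
  prof1 <- bin_and_transform(co$rpm, co$samples$age_since_L4, first_bin_norm = TRUE)
  expect_true(all(prof1$values[, 1] == 0))
  # zero-expression gene takes the zero-variance path with a warning
  v <- co$rpm$values
  v[1, ] <- 0
  expect_warning(pz <- bin_and_transform(v, co$samples$age_since_L4), "zero-variance")
  expect_true(all(pz$values[1, ] == 0))
})

test_that("z-scored profiles are invariant to per-gene rescaling of expression", {
  co <- small_cohort()
  v <- co$rpm$values
  v2 <- v * 5  # per-gene positive rescaling (values >> 1, log2(x+1) ~ log2 x + const)
  p1 <- bin_and_transform(v, co$samples$age_since_L4)
  p2 <- bin_and_transform(v2, co$samples$age_since_L4)
  expect_equal(p1$values, p2$values, tolerance = 0.05)
})

test_that("correlation distance matches its definition and limits", {
  a <- c(1, 2, 3, 5); b <- -a
  expect_equal(correlation_distance(a, a), 0)
  expect_equal(correlation_distance(a, b), 4)
  expect_equal(correlation_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)), 2)
  expect_warning(d0 <- correlation_distance(a, rep(2, 4)), "zero-variance")
  expect_equal(d0, 2)
  m <- rbind(g1 = a, g2 = b, g3 = c(2, 2, 7, 1))
  D <- as.matrix(correlation_distance(m))
  expect_equal(D, t(D))
  expect_equal(unname(D["g1", "g2"]), 4)
})

test_that("presquared Ward matches a brute-force Lance-Williams oracle", {
  set.seed(13)
  m <- matrix(rnorm(6 * 10), 6, 10)
  rownames(m) <- sprintf("g%d", 1:6)
  d <- correlation_distance(m)
  fit <- hcluster(m, k = 3, variant = "presquared")
  oracle <- bf_ward(d)
  expect_equal(fit$tree$height, oracle$heights, tolerance = 1e-10)
  for (step in 1:5) {
    k <- 6 - step
    expect_equal(adjusted_rand_index(stats::cutree(fit$tree, k), oracle$partitions[[step]]), 1)
  }
})

test_that("hcluster edge cases and order invariance", {
  co <- small_cohort()
  prof <- bin_and_transform(co$rpm, co$samples$age_since_L4)
  n <- nrow(prof$values)
  singletons <- hcluster(prof, k = n)
  expect_equal(length(unique(singletons$labels)), n)
  expect_error(hcluster(prof, k = 0), "k")
  expect_error(hcluster(prof, k = n + 1), "k")
  fit <- hcluster(prof, k = 8)
  set.seed(2)
  perm <- sample(n)
  fit_p <- hcluster(prof$values[perm, ], k = 8)
  expect_equal(
    adjusted_rand_index(fit$labels[rownames(prof$values)[perm]], fit_p$labels), 1
  )
})

test_that("planted archetypes are recovered and their means track the truth", {
  co <- small_cohort()
  fit <- cluster_preset(co$rpm, co$samples$age_since_L4, preset = "profiles", k = 8)
  truth <- co$truth$genes$archetype[match(names(fit$result$labels), co$truth$genes$gene_id)]
  expect_gte(adjusted_rand_index(fit$result$labels, truth), 0.9)
  means <- cluster_means(fit$result, fit$profiles)
  # oracle: the expectation of the pipeline's estimator on noise-free data --
  # each member's archetype evaluated at the actual sample ages (RPM scale
  # 1e6 * shape / n_genes), run through the same transform chain
  lib <- archetype_library(600)
  ages <- co$samples$age_since_L4
  rpm_scale <- 1e6 / nrow(co$rpm$values)
  truth_rpm <- t(vapply(rownames(co$rpm$values), function(g) {
    arch <- co$truth$genes$archetype[co$truth$genes$gene_id == g]
    rpm_scale * lib[[arch]]$fn(ages, co$truth$gene_params[[g]])
  }, numeric(length(ages))))
  colnames(truth_rpm) <- colnames(co$rpm$values)
  truth_prof <- bin_and_transform(truth_rpm, ages, first_bin_norm = TRUE)
  for (cl in rownames(means$mean)) {
    members <- names(fit$result$labels)[fit$result$labels == as.integer(cl)]
    arch <- unique(co$truth$genes$archetype[co$truth$genes$gene_id %in% members])
    expect_length(arch, 1)
    curve <- colMeans(truth_prof$values[members, , drop = FALSE])
    if (sd(curve) > 0) {
      expect_gt(cor(means$mean[cl, ], curve), 0.95)
    }
  }
})

test_that("cluster_means handles singletons and mirror pairs", {
  m <- rbind(a = c(1, 2, 3), b = c(-1, -2, -3), c = c(5, 5, 1))
  res <- structure(
    list(k = 2L, labels = c(a = 1L, b = 1L, c = 2L), sizes = c(2L, 1L)),
    class = "cluster_result"
  )
  cm <- cluster_means(res, m)
  expect_equal(unname(cm$mean["1", ]), c(0, 0, 0))
  expect_equal(unname(cm$mean["2", ]), c(5, 5, 1))
  expect_equal(unname(cm$sd["2", ]), c(0, 0, 0))
})

test_that("representative genes: exemplars win, ties break lexicographically", {
  # noise-free exemplar among noisy copies
  set.seed(31)
  t <- seq(0, 600, length.out = 12)
  base <- sin(2 * pi * t / 300)
  m <- rbind(
    exemplar = base,
    noisy1 = base + rnorm(12, 0, 0.6),
    noisy2 = base + rnorm(12, 0, 0.6),
    noisy3 = base + rnorm(12, 0, 0.6),
    other1 = t / 600, other2 = t / 600 + rnorm(12, 0, 0.05)
  )
  fit <- hcluster(m, k = 2, variant = "presquared")
  reps <- representative_genes(fit, m)
  expect_true("exemplar" %in% reps$gene_id)
  # singleton cluster: that gene with r = 1
  fitS <- hcluster(m, k = 6)
  repsS <- representative_genes(fitS, m)
  expect_true(all(repsS$r == 1))
  # numeric tie: two identical genes -> lexicographically smaller id
  tie <- rbind(zz = c(1, 2, 3, 4), aa = c(1, 2, 3, 4), bb = c(2, 4, 6, 8))
  resT <- structure(list(k = 1L, labels = c(zz = 1L, aa = 1L, bb = 1L), sizes = 3L),
                    class = "cluster_result")
  expect_equal(representative_genes(resT, tie)$gene_id, "aa")
})

test_that("markers preset routes through per-sample profiles", {
  co <- small_cohort()
  fit <- cluster_preset(co$rpm, preset = "markers", k = 10)
  expect_equal(fit$result$k, 10L)
  expect_equal(ncol(fit$profiles), ncol(co$rpm$values))
  reps <- representative_genes(fit$result, fit$profiles)
  expect_equal(nrow(reps), 10)
  expect_true(all(reps$gene_id %in% rownames(co$rpm$values)))
})
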