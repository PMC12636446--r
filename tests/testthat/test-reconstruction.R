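# Gap-correlation curves, alignment comparison, trajectory smoothing,
# embedding and artificial pooling.

test_that("pair correlations: duplicates give r=1, random profiles give r~0", {
  set.seed(5)
  v <- matrix(rnorm(400, 8, 2), 100, 4)
  v[, 2] <- v[, 1]  # duplicated sample, age gap 0
  rownames(v) <- sprintf("g%d", 1:100); colnames(v) <- sprintf("s%d", 1:4)
  pairs <- pair_correlations(v, ages = c(10, 10, 300, 500), use_log = FALSE)
  expect_equal(pairs$r[pairs$i == 1 & pairs$j == 2], 1)
  other <- pairs$r[!(pairs$i == 1 & pairs$j == 2)]
  expect_true(all(abs(other) < 3 / sqrt(100)))
})

test_that("gap curve accounts for every unordered pair exactly once", {
  co <- small_cohort()
  n <- ncol(co$rpm$values)
  curve <- pairwise_gap_correlations(co$rpm, co$samples$age_since_L4)
  expect_equal(sum(curve$n_pairs), n * (n - 1) / 2)
  expect_equal(nrow(attr(curve, "pairs")), n * (n - 1) / 2)
})

test_that("gap curve is exactly non-increasing on the stationary noise-free world", {
  st <- gen_stationary_cohort(n_individuals = 120, n_freqs = 32, seed = 6)
  curve <- pairwise_gap_correlations(rpm_normalize(st$counts),
                                     st$samples$age_since_L4, use_log = FALSE)
  m <- curve$mean_r[!is.na(curve$mean_r)]
  expect_true(all(diff(m) <= 1e-12))
})

test_that("constant samples are excluded with a warning", {
  v <- matrix(rnorm(30, 10), 10, 3)
  v[, 3] <- 4
  rownames(v) <- sprintf("g%d", 1:10); colnames(v) <- sprintf("s%d", 1:3)
  expect_warning(pairs <- pair_correlations(v, c(1, 2, 3), use_log = FALSE),
                 "constant-profile")
  expect_equal(nrow(pairs), 1)
})

test_that("compare_gap_groups: KS behaviour at the limits and under a shift", {
  same <- data.frame(gap = c(rep(2, 50), rep(100, 50)), r = rep(seq(0, 1, length.out = 50), 2))
  res <- compare_gap_groups(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # +0.2 shift at n=100 per group is decisive
  set.seed(7)
  shifted <- data.frame(
    gap = c(rep(2, 100), rep(100, 100)),
    r = c(rnorm(100, 0.9, 0.05), rnorm(100, 0.7, 0.05))
  )
  expect_lt(compare_gap_groups(shifted)$p_value, 1e-3)
  tiny <- data.frame(gap = c(1, 50), r = c(0.9, 0.5))
  expect_warning(low <- compare_gap_groups(tiny), "little power")
  expect_gte(low$p_value, 0.05)
  expect_error(compare_gap_groups(data.frame(gap = 1, r = 0.5)), "non-empty")
})

test_that("stage alignment beats hatch alignment exactly when jitter exists", {
  co0 <- gen_expression_cohort(expression_sim_config(
    n_individuals = 60, n_genes_per_archetype = 10, jitter_sd = 0, seed = 31
  ))
  r0 <- rpm_normalize(co0$counts)
  eq <- compare_alignments(r0, co0$samples$age_since_L4, co0$samples$age_since_hatch)
  expect_equal(eq$advantage, 0)       # pure shift: identical pair structure
  expect_equal(eq$ks_statistic, 0)

  adv <- vapply(c(0.05, 0.1), function(j) {
    co <- gen_expression_cohort(expression_sim_config(
      n_individuals = 120, n_genes_per_archetype = 10, jitter_sd = j, seed = 31
    ))
    al <- compare_alignments(rpm_normalize(co$counts),
                             co$samples$age_since_L4, co$samples$age_since_hatch)
    al$advantage
  }, numeric(1))
  expect_gt(adv[1], 0)
  expect_gt(adv[2], adv[1])           # doubling jitter widens the advantage
})

test_that("smooth_trajectory is an exact windowed mean and linear operator", {
  set.seed(9)
  ages <- runif(80, 0, 600)
  const <- smooth_trajectory(rep(3.3, 80), ages)
  expect_true(all(abs(const$value[!is.na(const$value)] - 3.3) < 1e-12))
  # windowed-mean oracle, coded independently
  y <- rnorm(80)
  tr <- smooth_trajectory(y, ages)
  half <- 1.45 * 60 / 2
  for (i in c(5, 20, 50)) {
    sel <- abs(ages - tr$time_min[i]) <= half
    expect_equal(tr$value[i], mean(y[sel]))
    expect_equal(tr$n[i], sum(sel))
  }
  # linear gene: smoothed value equals a + b * local age mean to 1e-9
  lin <- smooth_trajectory(2 + 0.5 * ages, ages)
  expected <- vapply(lin$time_min, function(t) {
    2 + 0.5 * mean(ages[abs(ages - t) <= half])
  }, numeric(1))
  expect_equal(lin$value, expected, tolerance = 1e-9)
  # linearity: smooth(aX + bY) = a smooth(X) + b smooth(Y), exactly
  x2 <- rnorm(80)
  lhs <- smooth_trajectory(2 * y - 3 * x2, ages)$value
  rhs <- 2 * tr$value - 3 * smooth_trajectory(x2, ages)$value
  expect_equal(lhs, rhs)
})

test_that("smoothing recovers oscillation peaks within a quarter hour", {
  co <- gen_expression_cohort(expression_sim_config(
    n_individuals = 193, n_genes_per_archetype = 1, archetypes = "oscillation",
    dispersion = 0.05, seed = 17
  ))
  p <- co$truth$gene_params[[1]]
  tr <- smooth_trajectory(co$counts$values[1, ], co$samples$age_since_L4)
  v <- tr$value
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  peaks <- peaks[v[peaks] > mean(v, na.rm = TRUE)]
  true_peaks <- p$phase + p$period / 4 + p$period * (0:3)
  true_peaks <- true_peaks[true_peaks > 0 & true_peaks < max(tr$time_min)]
  for (tp in true_peaks) {
    expect_lt(min(abs(tr$time_min[peaks] - tp)), 15)
  }
})

test_that("embedding is seeded, orders samples by age, and degrades under shuffling", {
  co <- small_cohort()
  expect_warning(
    emb <- embed_samples(co$rpm, co$samples$age_since_L4, seed = 2, n_iter = 250),
    "perplexity clamped"
  )
  emb2 <- suppressWarnings(embed_samples(co$rpm, co$samples$age_since_L4,
                                         seed = 2, n_iter = 250))
  expect_identical(emb$coords, emb2$coords)
  expect_lt(emb$mean_knn_age_gap, emb$mean_pairwise_age_gap / 2)

  set.seed(4)
  shuf <- apply(co$rpm$values, 2, sample)
  rownames(shuf) <- rownames(co$rpm$values)
  embS <- suppressWarnings(embed_samples(shuf, co$samples$age_since_L4,
                                         seed = 2, n_iter = 250))
  expect_gt(embS$mean_knn_age_gap, emb$mean_knn_age_gap * 3)
  expect_error(embed_samples(co$rpm$values[, 1:3], c(1, 2, 3)), "more than 3 samples")
})

test_that("artificial pooling fills hourly bins as the design dictates", {
  co <- small_cohort()
  v <- co$rpm$values
  # all samples at exactly one center
  one <- artificial_pool(v, rep(1800, ncol(v)))
  expect_equal(ncol(one$values), 1)
  expect_equal(one$values[, 1], rowMeans(v))
  # uniform ages over 10 h -> 10 populated bins with ~n/10 samples each
  set.seed(11)
  ages <- runif(200, 1830, 2430)  # centers 31..40 h
  pooled <- artificial_pool(v[, sample(ncol(v), 200, replace = TRUE)], ages)
  expect_equal(length(pooled$centers_h), 10)
  expect_true(all(abs(pooled$n_per_bin - 20) < 15))
})

test_that("reference comparison separates matched and shuffled references", {
  co <- small_cohort()
  set.seed(21)
  ages <- co$samples$age_since_L4 + 1830
  pooled <- artificial_pool(co$rpm, ages)
  self <- compare_to_reference(pooled, pooled, hour_offset = 0)
  expect_true(all(self$per_gene$r > 1 - 1e-9))
  expect_lt(self$t_p, 1e-3)
  expect_gt(self$mean_r, self$mean_r_shuffled)
  # offset alignment: shift reference centers by 2 h and ask for offset 2
  ref <- pooled
  ref$centers_h <- ref$centers_h - 2
  off <- compare_to_reference(pooled, ref, hour_offset = 2)
  expect_true(all(off$per_gene$r > 1 - 1e-9))
  # constant reference gene is excluded with a warning
  ref2 <- pooled
  ref2$values[3, ] <- 5
  expect_warning(cc <- compare_to_reference(pooled, ref2, 0), "constant gene")
  expect_false(rownames(pooled$values)[3] %in% cc$per_gene$gene_id)
  expect_error(compare_to_reference(pooled, ref, hour_offset = 50), "3 shared bins")
})
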