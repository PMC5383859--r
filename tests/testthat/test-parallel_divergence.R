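# Parallel-divergence machinery: quantile outlier sets, shared counts,
# permutation null vs the closed-form oracle, and spiked-outlier power.

test_that("outlier sets contain the loci strictly above the quantile", {
  # 100 distinct values at q = 0.99: exactly the maximum lies above
  tbl <- tibble::tibble(locus_id = paste0("L", 1:100),
                        T1 = seq(0.001, 0.1, length.out = 100))
  sets <- outlier_sets(tbl, 0.99, min_defined = 50)
  expect_identical(sets$T1, "L100")
  # all values tied: nothing strictly above
  tied <- tibble::tibble(locus_id = paste0("L", 1:200), T1 = rep(0.02, 200))
  expect_length(outlier_sets(tied, 0.97, min_defined = 50)$T1, 0L)
  # rank arithmetic at the study scale: 180 or 181 loci above the 99th
  set.seed(8)
  big <- tibble::tibble(locus_id = paste0("L", 1:18073), T1 = runif(18073))
  n_out <- length(outlier_sets(big, 0.99)$T1)
  expect_true(n_out %in% c(180L, 181L))
  expect_error(outlier_sets(tbl[1:50, ], 0.99), "defined loci")
})

test_that("count_shared follows inclusion-exclusion", {
  expect_equal(count_shared(list(1:10, 5:14, 9:18)),
               c(exactly2 = 8, exactly3 = 2))
  expect_equal(count_shared(list(1:3, 4:6, 7:9)), c(exactly2 = 0, exactly3 = 0))
  expect_equal(count_shared(list(1:5, 1:5, 1:5)), c(exactly2 = 0, exactly3 = 5))
  # bookkeeping identity on random sets
  set.seed(2)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample.int(60, sample(5:30, 1)))
    cnt <- count_shared(sets)
    pair_sum <- length(intersect(sets[[1]], sets[[2]])) +
      length(intersect(sets[[1]], sets[[3]])) +
      length(intersect(sets[[2]], sets[[3]]))
    expect_equal(pair_sum, cnt[["exactly2"]] + 3 * cnt[["exactly3"]])
  }
})

test_that("analytic expectations match hand arithmetic and edge cases", {
  e <- analytic_expectation(180, 180, 180, 18073)
  expect_equal(e[["exactly2"]], 3 * 180^2 * (18073 - 180) / 18073^2)
  expect_equal(e[["exactly2"]], 5.323, tolerance = 1e-3)
  expect_equal(e[["exactly3"]], 180^3 / 18073^2)
  expect_equal(analytic_expectation(542, 542, 542, 18073)[["exactly2"]],
               47.30, tolerance = 1e-3)
  expect_equal(analytic_expectation(0, 100, 100, 1000),
               c(exactly2 = 10, exactly3 = 0))
})

test_that("permutation null converges to the analytic expectation", {
  set.seed(5)
  for (i in 1:5) {
    L <- sample(500:4000, 1)
    sizes <- sample.int(round(L / 10), 3)
    nul <- permutation_null(sizes, L, n_perm = 2000, seed = i)
    ana <- analytic_expectation(sizes[1], sizes[2], sizes[3], L)
    se2 <- nul$expected2_sd / sqrt(2000)
    se3 <- nul$expected3_sd / sqrt(2000)
    expect_lt(abs(nul$expected2_mean - ana[["exactly2"]]), 3 * se2 + 1e-9)
    expect_lt(abs(nul$expected3_mean - ana[["exactly3"]]), 3 * se3 + 1e-9)
  }
  # saturation: all three sets are everything
  sat <- permutation_null(c(50, 50, 50), 50, n_perm = 50, seed = 1)
  expect_equal(sat$expected3_mean, 50)
  expect_equal(sat$expected2_mean, 0)
})

test_that("contrast F_ST flags fixed differences and undefined loci", {
  samples <- make_samples(3)
  n <- nrow(samples)
  comp <- matrix(1, n, 3)
  # locus 1 fixed-different between T1 high and low; others at p = 0.5
  comp[, 1] <- ifelse(samples$site_id == "T1_H", 2,
                      ifelse(samples$site_id == "T1_L", 0, 1))
  # locus 3 monomorphic everywhere -> undefined in every contrast
  comp[, 3] <- 0
  rownames(comp) <- samples$individual_id
  gm <- fit_from_composite(comp, samples)
  tbl <- contrast_fst(gm, samples)
  expect_equal(tbl$T1[1], 1.0)
  expect_true(all(is.na(tbl$T1[3])))
  expect_identical(names(tbl), c("locus_id", "T1", "T2", "T3"))
})

test_that("spiked parallel outliers are detected; background is null", {
  hits <- vapply(1:8, function(s) {
    cfg <- sim_config(n_loci = 1200, samples_per_site = 20,
                      n_outlier_loci = 40, outlier_delta = 0.3,
                      seed = 900 + s)
    truth <- simulate_genotypes(simulate_site_frequencies(cfg))
    gm <- fit_from_composite(truth$true_genotypes * 1.0, truth$samples)
    pd <- parallel_divergence_test(gm, truth$samples, quantiles = 0.99,
                                   n_perm = 500, seed = s)
    pd$observed_exactly2 + pd$observed_exactly3 > pd$expected2_hi95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # no outliers: observed counts compatible with the null
  inside <- vapply(1:8, function(s) {
    cfg <- sim_config(n_loci = 1200, samples_per_site = 20, seed = 300 + s)
    truth <- simulate_genotypes(simulate_site_frequencies(cfg))
    gm <- fit_from_composite(truth$true_genotypes * 1.0, truth$samples)
    pd <- parallel_divergence_test(gm, truth$samples, quantiles = 0.99,
                                   n_perm = 500, seed = s)
    pd$observed_exactly2 >= pd$expected2_lo95 &
      pd$observed_exactly2 <= pd$expected2_hi95
  }, logical(1))
  expect_gte(mean(inside), 0.6)
})

test_that("spiked loci rank above the 99th percentile of each contrast", {
  cfg <- sim_config(n_loci = 1500, samples_per_site = 25, n_outlier_loci = 15,
                    outlier_delta = 0.3, seed = 77)
  truth <- simulate_genotypes(simulate_site_frequencies(cfg))
  gm <- fit_from_composite(truth$true_genotypes * 1.0, truth$samples)
  tbl <- contrast_fst(gm, truth$samples)
  out <- match(truth$outlier_locus_ids, tbl$locus_id)
  above <- vapply(c("T1", "T2", "T3"), function(cn) {
    thr <- quantile(tbl[[cn]], 0.99, na.rm = TRUE)
    mean(tbl[[cn]][out] > thr)
  }, numeric(1))
  expect_gt(mean(above), 0.8)
})
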