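# Gibbs genotype model: oracle equivalence, prior/likelihood limits,
# reproducibility, and the certainty mask.

# Independent oracle: exact posterior genotype probabilities for one locus
# and a handful of individuals, by summing over all genotype combinations and
# integrating the flat-prior allele frequency on a fine grid.
grid_posterior <- function(lik_triples, grid_step = 1e-4) {
  n <- nrow(lik_triples)
  p <- seq(grid_step / 2, 1 - grid_step / 2, by = grid_step)
  combos <- as.matrix(expand.grid(rep(list(0:2), n)))
  post <- matrix(0, n, 3)
  total <- 0
  for (r in seq_len(nrow(combos))) {
    g <- combos[r, ]
    likprod <- prod(lik_triples[cbind(seq_len(n), g + 1L)])
    alt <- sum(g); ref <- 2 * n - alt
    n_het <- sum(g == 1L)
    # integral over p of prod HWE(g_i | p) = 2^het * p^alt * (1-p)^ref
    weight <- likprod * 2^n_het * mean(p^alt * (1 - p)^ref)
    total <- total + weight
    for (i in seq_len(n)) post[i, g[i] + 1L] <- post[i, g[i] + 1L] + weight
  }
  post / total
}

test_that("Gibbs posterior matches direct numerical integration (small cases)", {
  cases <- list(
    rbind(c(1, 1e-2, 1e-6)),                       # one individual, ref-ish
    rbind(c(1, 0.3, 0.01), c(0.05, 1, 0.05)),      # two individuals
    rbind(c(1, 1, 1), c(1e-4, 1, 1e-4), c(1e-8, 1e-2, 1)))  # three, one blank
  for (k in seq_along(cases)) {
    lik <- cases[[k]]
    n <- nrow(lik)
    arr <- array(NA_real_, c(n, 1, 3))
    arr[, 1, ] <- lik
    loci <- tibble::tibble(locus_id = "L1", contig_id = "c1", pos = 1L,
                           ref = "A", alt = "G")
    gl <- gl_matrix(paste0("i", seq_len(n)), loci, arr,
                    matrix(5L, n, 1))
    samples <- tibble::tibble(individual_id = paste0("i", seq_len(n)),
                              site_id = "S1", transect_id = "T1",
                              elevation_class = "high",
                              latitude = 39, longitude = -120,
                              elevation_m = 2000)
    fit <- fit_genotype_model(gl, samples,
                              mcmc_settings(n_steps = 30000, burn_in = 5000,
                                            thin = 1, seed = 42,
                                            grouping = "pooled"))
    oracle <- grid_posterior(lik)
    expect_equal(fit$posterior[, 1, ], oracle, tolerance = 0.011,
                 ignore_attr = TRUE)
  }
})

test_that("zero-coverage individuals are informed by the site prior", {
  # 20 individuals with certain genotypes at p ~ 0.8, 5 with no reads
  set.seed(1)
  geno <- matrix(rbinom(20 * 40, 2, 0.8), 20, 40)
  gl_known <- gl_from_genotypes(geno)
  n <- 25; l <- 40
  lik <- array(1e-12, c(n, l, 3))
  lik[1:20, , ] <- gl_known$likelihoods
  lik[21:25, , ] <- 1
  dep <- rbind(matrix(8L, 20, l), matrix(0L, 5, l))
  gl <- gl_matrix(paste0("i", 1:25), gl_known$loci, lik, dep)
  samples <- tibble::tibble(individual_id = paste0("i", 1:25), site_id = "S1",
                            transect_id = "T1", elevation_class = "high",
                            latitude = 39, longitude = -120, elevation_m = 2000)
  fit <- fit_genotype_model(gl, samples, mcmc_settings(seed = 3))
  p_hat <- fit$allele_freqs[1, ]
  for (i in 21:25) {
    hwe <- cbind((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    expect_equal(fit$posterior[i, , ], hwe, tolerance = 0.05,
                 ignore_attr = TRUE)
    expect_equal(fit$composite[i, ], 2 * p_hat, tolerance = 0.1,
                 ignore_attr = TRUE)
  }
})

test_that("high coverage overwhelms the prior", {
  # one individual fixed alt (d = 50, k = 50) among refs: composite >= 1.98
  eps <- 0.01
  n <- 10; l <- 5
  lik <- array(NA_real_, c(n, l, 3))
  for (j in seq_len(l)) {
    for (i in seq_len(n)) lik[i, j, ] <- c(1, 1e-10, 1e-20)  # strong ref
    lik[1, j, ] <- c(dbinom(50, 50, eps), dbinom(50, 50, 0.5),
                     dbinom(50, 50, 1 - eps))
    lik[1, j, ] <- lik[1, j, ] / max(lik[1, j, ])
  }
  loci <- tibble::tibble(locus_id = paste0("L", 1:l),
                         contig_id = paste0("c", 1:l), pos = 1L,
                         ref = "A", alt = "G")
  gl <- gl_matrix(paste0("i", 1:n), loci, lik, matrix(50L, n, l))
  samples <- tibble::tibble(individual_id = paste0("i", 1:n), site_id = "S1",
                            transect_id = "T1", elevation_class = "high",
                            latitude = 39, longitude = -120, elevation_m = 2000)
  fit <- fit_genotype_model(gl, samples, mcmc_settings(seed = 7))
  expect_true(all(fit$composite[1, ] >= 1.98))
})

test_that("posterior triples sum to one and match the composite", {
  sim <- simulate_gbs(sim_config(n_loci = 60, samples_per_site = 4, seed = 13))
  fit <- fit_genotype_model(sim$gl, sim$samples, mcmc_settings(seed = 2))
  sums <- fit$posterior[, , 1] + fit$posterior[, , 2] + fit$posterior[, , 3]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-8)
  comp <- fit$posterior[, , 2] + 2 * fit$posterior[, , 3]
  expect_equal(unname(fit$composite), comp, tolerance = 1e-8)
  expect_true(all(fit$allele_freqs >= 0 & fit$allele_freqs <= 1))
})

test_that("composite converges to truth as depth grows and chains agree", {
  cfg <- sim_config(n_loci = 80, samples_per_site = 4, depth_mean = 100,
                    depth_dispersion = 1e6, seed = 31)
  sim <- simulate_gbs(cfg)
  fit <- fit_genotype_model(sim$gl, sim$samples, mcmc_settings(seed = 5))
  expect_lt(mean(abs(fit$composite - sim$truth$true_genotypes)), 0.01)
  # MCMC stability across independent seeds
  sim2 <- simulate_gbs(sim_config(n_loci = 60, samples_per_site = 4, seed = 17))
  f1 <- fit_genotype_model(sim2$gl, sim2$samples, mcmc_settings(seed = 101))
  f2 <- fit_genotype_model(sim2$gl, sim2$samples, mcmc_settings(seed = 202))
  expect_lt(sqrt(mean((f1$composite - f2$composite)^2)), 0.02)
})

test_that("adding alt reads never decreases the composite", {
  eps <- 0.01
  n <- 6; d <- 10
  samples <- tibble::tibble(individual_id = paste0("i", 1:n), site_id = "S1",
                            transect_id = "T1", elevation_class = "high",
                            latitude = 39, longitude = -120, elevation_m = 2000)
  comp_at_k <- vapply(0:10, function(k) {
    lik <- array(NA_real_, c(n, 1, 3))
    for (i in 1:n) lik[i, 1, ] <- c(0.5, 1, 0.5)  # weakly het background
    lik[1, 1, ] <- c(dbinom(k, d, eps), dbinom(k, d, 0.5), dbinom(k, d, 1 - eps))
    loci <- tibble::tibble(locus_id = "L1", contig_id = "c1", pos = 1L,
                           ref = "A", alt = "G")
    gl <- gl_matrix(paste0("i", 1:n), loci, lik, matrix(d, n, 1))
    fit <- fit_genotype_model(gl, samples, mcmc_settings(seed = 11))
    fit$composite[1, 1]
  }, numeric(1))
  expect_true(all(diff(comp_at_k) > -0.03))  # monotone up to MCMC jitter
  expect_lt(comp_at_k[1], 0.2)
  expect_gt(comp_at_k[11], 1.8)
})

test_that("certainty mask keeps near-integer composites, boundary inclusive", {
  comp <- matrix(c(0.08, 0.5, 1.10, 1.89, 0.11, 0.85), 2, 3,
                 dimnames = list(c("a", "b"), NULL))
  mask <- genotype_certainty_mask(comp, tol = 0.1)
  expect_identical(as.vector(mask), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_error(genotype_certainty_mask(comp, tol = 0.5), "overlap")
})

test_that("model errors on incomplete metadata or empty groups", {
  sim <- simulate_gbs(sim_config(n_loci = 10, samples_per_site = 2, seed = 1))
  expect_error(fit_genotype_model(sim$gl, sim$samples[-1, ]), "missing")
})
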