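# PCA, PERMANOVA (with vegan as independent oracle), and DAPC.

test_that("PCA has the expected rank-1 and symmetry behaviour", {
  comp <- rbind(a = c(0, 0, 0, 0), b = c(2, 2, 2, 2))
  res <- pca_genotypes(comp)
  expect_equal(res$pct_variance[1], 100)
  # duplicated individuals get identical scores
  comp2 <- rbind(a = c(0, 1, 2), a2 = c(0, 1, 2), b = c(2, 1, 0), c = c(1, 1, 1))
  res2 <- pca_genotypes(comp2)
  expect_equal(res2$scores["a", ], res2$scores["a2", ], ignore_attr = TRUE)
  expect_equal(sum(res2$pct_variance), 100, tolerance = 1e-6)
  expect_equal(max(abs(colMeans(res2$scores))), 0, tolerance = 1e-10)
})

test_that("unstructured data spreads variance across many axes", {
  set.seed(5)
  comp <- matrix(rbinom(50 * 1000, 2, 0.5), 50, 1000) * 1.0
  rownames(comp) <- paste0("i", 1:50)
  res <- pca_genotypes(comp)
  expect_lt(res$pct_variance[1], 2 * mean(res$pct_variance))
})

test_that("PERMANOVA matches vegan::adonis2 on the same distances", {
  skip_if_not_installed("vegan")
  set.seed(2)
  pts <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("a", "b", "c", "d"), each = 5)
  ours <- permanova(pts, labels, n_perm = 199, seed = 1)
  veg <- vegan::adonis2(stats::dist(pts) ~ g,
                        data = data.frame(g = labels), permutations = 199)
  expect_equal(ours$r2, veg$R2[1], tolerance = 1e-10)
  expect_equal(ours$f, veg$F[1], tolerance = 1e-10)
  expect_equal(ours$df_between, veg$Df[1])
})

test_that("PERMANOVA separates distinct centroids and is order-invariant", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 20, 0.1), 5, 2))
  labels <- rep(c("lo", "hi"), each = 5)
  res <- permanova(pts, labels, n_perm = 999, seed = 4)
  # permutations recreating the observed 5/5 partition tie with F_obs, so the
  # attainable floor is slightly above 1/(n_perm + 1)
  expect_lte(res$p, 0.01)
  # permuting the input order leaves R2 and F unchanged
  ord <- sample(10)
  res2 <- permanova(pts[ord, ], labels[ord], n_perm = 99, seed = 4)
  expect_equal(res2$r2, res$r2)
  expect_equal(res2$f, res$f)
  expect_error(permanova(pts, c(rep("a", 9), "b")), "2 members")
})

test_that("DAPC cluster search finds the constructed k", {
  # k-means BIC operates in a PC space of realistic dimension (the k-means
  # step conventionally keeps many PCs; in 1-2 dimensions splitting Gaussian
  # noise always reduces WSS enough to defeat the k ln N penalty)
  d <- 40
  set.seed(3)
  blobs <- rbind(matrix(rnorm(30 * d), 30, d),
                 matrix(rnorm(30 * d), 30, d))
  blobs[31:60, 1] <- blobs[31:60, 1] + 10  # separation 10 s.d. on one axis
  res <- dapc_find_clusters(blobs, n_pcs = d, k_max = 5, seed = 1)
  expect_equal(res$best_k, 2L)
  expect_equal(res$bic_by_k$k, 1:5)
  # forced single cluster
  expect_equal(dapc_find_clusters(blobs, n_pcs = d, k_max = 1, seed = 1)$best_k, 1L)
  # single isotropic blob: k = 1 in most seeds
  ks <- vapply(1:10, function(s) {
    x <- matrix(rnorm(100 * 60), 100, 60)
    dapc_find_clusters(x, n_pcs = 60, k_max = 4, seed = s)$best_k
  }, integer(1))
  expect_gte(mean(ks == 1L), 0.9)
  expect_error(dapc_find_clusters(blobs, n_pcs = d, k_max = 60), "below")
})

test_that("DAPC assignments are calibrated and match MASS::lda posteriors", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
             matrix(rnorm(100, 10, 1), 50, 2))
  rownames(x) <- paste0("i", 1:100)
  lab <- rep(1:2, each = 50)
  res <- dapc_assign(x, lab, n_pcs = 2)
  expect_equal(unname(rowSums(res$assignments)), rep(1, 100), tolerance = 1e-8)
  own <- res$assignments[cbind(1:100, lab)]
  expect_true(all(own > 0.99))
  # oracle: Gaussian LDA posteriors from MASS on the same data
  ld <- MASS::lda(x, grouping = lab)
  post <- stats::predict(ld, x)$posterior
  expect_equal(unname(res$assignments), unname(post), tolerance = 1e-6)
  # duplicated individual gets an identical assignment row
  x2 <- rbind(x, x[1, , drop = FALSE])
  res2 <- dapc_assign(x2, c(lab, 1), n_pcs = 2)
  expect_equal(res2$assignments[101, ], res2$assignments[1, ],
               ignore_attr = TRUE)
})

test_that("fully overlapping clusters give ~symmetric assignments", {
  set.seed(12)
  x <- matrix(rnorm(400), 200, 2)
  lab <- rep(1:2, each = 100)
  res <- dapc_assign(x, lab, n_pcs = 2)
  own <- res$assignments[cbind(1:200, lab)]
  expect_lt(abs(mean(own) - 0.5), 0.1)
})
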