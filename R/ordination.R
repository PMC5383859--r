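# Multivariate structure: PCA on the genotype covariance structure, PERMANOVA
# on ordination axes, and DAPC (k-means cluster search + Gaussian LDA).

#' PCA of composite genotypes
#'
#' Column-centred (unscaled) singular-value decomposition of the individuals x
#' loci composite-genotype matrix — PCA on the genotype covariance matrix.
#'
#' @param gm A `genotype_fit` or bare composite matrix (no missing values).
#' @return List of class `ordination_result`: `scores` (N x K),
#'   `pct_variance` (length K, sums to 100), `loadings`, `samples`.
#' @export
pca_genotypes <- function(gm) {
  comp <- if (inherits(gm, "genotype_fit")) gm$composite else gm
  stopifnot(nrow(comp) >= 2L, ncol(comp) >= 2L, !anyNA(comp))
  fit <- prcomp(comp, center = TRUE, scale. = FALSE)
  tot <- sum(fit$sdev^2)
  pct <- if (tot == 0) rep(0, length(fit$sdev)) else 100 * fit$sdev^2 / tot
  structure(list(scores = fit$x, pct_variance = pct, loadings = fit$rotation,
                 constant = tot == 0,
                 samples = if (inherits(gm, "genotype_fit")) gm$samples else NULL),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result> ", nrow(x$scores), " individuals, ",
      ncol(x$scores), " axes; PC1+PC2 = ",
      format(sum(x$pct_variance[1:min(2, length(x$pct_variance))]),
             digits = 3), "% variance\n", sep = "")
  invisible(x)
}

#' Tidy ordination scores
#'
#' @param x An `ordination_result`.
#' @param n_axes Number of axes to keep (default 2).
#' @param ... Unused.
#' @return Tibble of individual scores joined to sample metadata when present.
#' @export
tidy.ordination_result <- function(x, n_axes = 2, ...) {
  n_axes <- min(n_axes, ncol(x$scores))
  out <- tibble::as_tibble(x$scores[, seq_len(n_axes), drop = FALSE])
  out <- dplyr::mutate(out, individual_id = rownames(x$scores),
                       .before = 1)
  if (!is.null(x$samples)) {
    out <- dplyr::left_join(out, tibble::as_tibble(x$samples),
                            by = "individual_id")
  }
  out
}

#' PERMANOVA on ordination axes
#'
#' Permutational multivariate analysis of variance on the Euclidean distances
#' of a points matrix (typically the first two ordination axes). Sums of
#' squares are computed from the squared distance matrix
#' (`SS_total = sum_{i<j} d_ij^2 / N`; within-group terms divided by group
#' size); the pseudo-F is `(SS_between/(a-1)) / (SS_within/(N-a))` and the
#' p-value counts permuted statistics at least as large as the observed one,
#' including the observed in the null set.
#'
#' @param points N x k numeric matrix of coordinates.
#' @param labels Grouping vector of length N (each group >= 2 members).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return One-row tibble of class `permanova_result`: `r2`, `f`, `p`,
#'   degrees of freedom, `n_perm`.
#' @export
permanova <- function(points, labels, n_perm = 999L, seed = 1L) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  n <- nrow(points)
  stopifnot(length(labels) == n, nlevels(labels) >= 2L)
  if (any(table(labels) < 2L)) stop("every group needs at least 2 members")
  d2 <- as.matrix(stats::dist(points))^2
  groups <- lapply(levels(labels), function(g) which(labels == g))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(groups) {
    sum(vapply(groups, function(idx) {
      sub <- d2[idx, idx, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(idx)
    }, numeric(1)))
  }
  a <- nlevels(labels)
  f_for <- function(groups) {
    ssw <- ss_within_for(groups)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_for(groups)
  ss_within <- ss_within_for(groups)
  set.seed(seed)
  sizes <- lengths(groups)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    idx <- split(perm, rep(seq_along(sizes), sizes))
    if (f_for(idx) >= f_obs) exceed <- exceed + 1L
  }
  out <- tibble::tibble(
    r2 = (ss_total - ss_within) / ss_total,
    f = f_obs,
    df_between = a - 1L, df_within = n - a,
    p = (1 + exceed) / (1 + n_perm),
    n_perm = as.integer(n_perm))
  class(out) <- c("permanova_result", class(out))
  out
}

#' DAPC cluster search (k-means + BIC)
#'
#' For each candidate k, runs k-means (10 restarts) on the first `n_pcs`
#' PCA scores and scores the solution with `BIC = N ln(WSS/N) + k ln(N)`;
#' the most likely number of clusters minimises BIC.
#'
#' @param scores PCA score matrix (or `ordination_result`).
#' @param n_pcs Number of leading PCs to use.
#' @param k_max Largest number of clusters tried (must be < N).
#' @param seed Integer seed.
#' @return List of class `dapc_clusters`: `bic_by_k` tibble, `best_k`,
#'   `cluster_labels`.
#' @export
dapc_find_clusters <- function(scores, n_pcs = 1L, k_max = 6L, seed = 1L) {
  if (inherits(scores, "ordination_result")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max >= n) stop("k_max must be below the number of individuals")
  stopifnot(n_pcs <= ncol(scores))
  x <- scores[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) {
    if (k == 1L) {
      wss <- sum(scale(x, scale = FALSE)^2)
      list(wss = wss, cluster = rep(1L, n))
    } else {
      km <- kmeans(x, centers = k, nstart = 10, iter.max = 300)
      list(wss = km$tot.withinss, cluster = km$cluster)
    }
  })
  bic <- vapply(seq_len(k_max), function(k) {
    n * log(fits[[k]]$wss / n) + k * log(n)
  }, numeric(1))
  best <- which.min(bic)
  structure(list(
    bic_by_k = tibble::tibble(k = seq_len(k_max), bic = bic),
    best_k = best,
    cluster_labels = fits[[best]]$cluster),
    class = "dapc_clusters")
}

#' DAPC assignment probabilities
#'
#' Linear discriminant analysis on the retained PCs with the k-means cluster
#' labels: discriminant axes maximise among-cluster variance, and assignment
#' probabilities come from the equal-covariance Gaussian model in the
#' `n_da`-dimensional discriminant space. A singular pooled within-cluster
#' covariance is ridge-regularised (the epsilon used is recorded).
#'
#' @param scores PCA score matrix (or `ordination_result`).
#' @param cluster_labels Integer cluster labels (>= 2 clusters).
#' @param n_pcs PCs retained.
#' @param n_da Discriminant axes retained (at most clusters - 1).
#' @return List of class `dapc_result`: `assignments` (N x k, rows sum to 1),
#'   `cluster_labels`, `discriminants` (N x n_da), `ridge_epsilon`.
#' @export
dapc_assign <- function(scores, cluster_labels, n_pcs = 1L, n_da = NULL) {
  if (inherits(scores, "ordination_result")) scores <- scores$scores
  x <- as.matrix(scores)[, seq_len(n_pcs), drop = FALSE]
  lab <- as.integer(as.factor(cluster_labels))
  k <- max(lab)
  if (k < 2L) stop("need at least 2 clusters")
  n <- nrow(x); p <- ncol(x)
  if (is.null(n_da)) n_da <- min(k - 1L, p)
  stopifnot(n_da >= 1L, n_da <= k - 1L, n_da <= p)
  means <- rowsum(x, lab) / as.vector(table(lab))
  centred <- x - means[lab, , drop = FALSE]
  W <- crossprod(centred) / (n - k)
  eps <- 0
  if (rcond_sym(W) < 1e-10) {
    eps <- 1e-8 * mean(diag(W)) + 1e-12
    W <- W + diag(eps, p)
  }
  B <- crossprod(sqrt(as.vector(table(lab))) *
                   (means - matrix(colMeans(x), k, p, byrow = TRUE))) / (k - 1)
  # discriminant axes: eigenvectors of W^{-1} B via symmetric whitening
  es_w <- eigen(W, symmetric = TRUE)
  w_inv_sqrt <- es_w$vectors %*% diag(1 / sqrt(pmax(es_w$values, 1e-12)),
                                      p) %*% t(es_w$vectors)
  es <- eigen(w_inv_sqrt %*% B %*% w_inv_sqrt, symmetric = TRUE)
  axes <- w_inv_sqrt %*% es$vectors[, seq_len(n_da), drop = FALSE]
  z <- x %*% axes
  zm <- means %*% axes
  # equal-covariance Gaussian posteriors in discriminant space (identity cov
  # after whitening by construction; use pooled covariance of z for safety)
  zc <- z - zm[lab, , drop = FALSE]
  S <- crossprod(zc) / (n - k)
  if (rcond_sym(S) < 1e-10) S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, ncol(S))
  S_inv <- solve(S)
  prior <- as.vector(table(lab)) / n
  logd <- sapply(seq_len(k), function(c) {
    dz <- sweep(z, 2, zm[c, ], "-")
    -0.5 * rowSums((dz %*% S_inv) * dz) + log(prior[c])
  })
  logd <- logd - apply(logd, 1, max)
  post <- exp(logd)
  post <- post / rowSums(post)
  rownames(post) <- rownames(scores)
  structure(list(assignments = post, cluster_labels = lab,
                 discriminants = z, ridge_epsilon = eps),
            class = "dapc_result")
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Tidy DAPC assignments
#'
#' @param x A `dapc_result`.
#' @param ... Unused.
#' @return Long tibble: `individual_id`, `cluster`, `probability`.
#' @export
tidy.dapc_result <- function(x, ...) {
  k <- ncol(x$assignments)
  ids <- rownames(x$assignments)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(x$assignments)))
  tibble::tibble(
    individual_id = rep(ids, times = k),
    cluster = rep(seq_len(k), each = nrow(x$assignments)),
    probability = as.vector(x$assignments))
}
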