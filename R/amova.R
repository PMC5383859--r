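# Hierarchical AMOVA on composite-genotype vectors: variance among transects,
# among elevation sites within transects, and within sites, with
# phi-statistics and level-specific permutation tests.

# Squared Euclidean distances between individuals over pairwise-complete loci,
# rescaled by the fraction of loci compared (missing entries = NA).
pairwise_sq_distances <- function(comp) {
  L <- ncol(comp)
  obs <- !is.na(comp)
  x <- comp
  x[!obs] <- 0
  # sum over shared loci of (xi - xj)^2 = xi^2 + xj^2 - 2 xi xj, restricted
  # to loci observed in both
  sq <- x^2
  shared <- tcrossprod(obs * 1)            # number of loci compared
  cross <- tcrossprod(x * obs)             # here x already zeroed at missing
  si <- (sq * 1) %*% t(obs * 1)            # sum of xi^2 over loci shared with j
  d2 <- si + t(si) - 2 * cross
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("a pair of individuals shares no observed loci")
  }
  d2 <- d2 * (L / shared)
  diag(d2) <- 0
  d2
}

# nested sums of squares from a squared-distance matrix
amova_ss <- function(d2, site, transect) {
  n <- nrow(d2)
  tri_sum <- function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)])
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_wp <- sum(vapply(split(seq_len(n), site), function(idx) {
    tri_sum(idx) / length(idx)
  }, numeric(1)))
  ss_wg <- sum(vapply(split(seq_len(n), transect), function(idx) {
    tri_sum(idx) / length(idx)
  }, numeric(1)))
  list(total = ss_total,
       among_groups = ss_total - ss_wg,
       among_pops_within = ss_wg - ss_wp,
       within_pops = ss_wp)
}

# unequal-sample-size coefficients for the nested moment equations
amova_coefficients <- function(site, transect) {
  n_p <- table(site)
  pop_group <- tapply(as.character(transect), site, function(v) v[1])
  n_g <- tapply(as.vector(n_p), pop_group, sum)
  N <- sum(n_p)
  P <- length(n_p); G <- length(n_g)
  sum_np2_over_ng <- sum(tapply(as.vector(n_p)^2, pop_group, sum) / n_g)
  n_prime <- (N - sum_np2_over_ng) / (P - G)
  n_dprime <- (sum_np2_over_ng - sum(n_p^2) / N) / (G - 1)
  n_tprime <- (N - sum(n_g^2) / N) / (G - 1)
  list(n_prime = n_prime, n_dprime = n_dprime, n_tprime = n_tprime,
       N = N, P = P, G = G)
}

amova_components <- function(d2, site, transect) {
  ss <- amova_ss(d2, site, transect)
  cf <- amova_coefficients(site, transect)
  df_a <- cf$G - 1
  df_b <- cf$P - cf$G
  df_c <- cf$N - cf$P
  ms_a <- ss$among_groups / df_a
  ms_b <- ss$among_pops_within / df_b
  ms_c <- ss$within_pops / df_c
  sigma_c <- ms_c
  sigma_b <- (ms_b - sigma_c) / cf$n_prime
  sigma_a <- (ms_a - sigma_c - cf$n_dprime * sigma_b) / cf$n_tprime
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       ss = ss, df = c(df_a, df_b, df_c))
}

phi_stats <- function(comp3) {
  tot <- comp3$sigma_a + comp3$sigma_b + comp3$sigma_c
  list(phi_CT = comp3$sigma_a / tot,
       phi_SC = comp3$sigma_b / (comp3$sigma_b + comp3$sigma_c),
       phi_ST = (comp3$sigma_a + comp3$sigma_b) / tot)
}

#' Hierarchical AMOVA with permutation tests
#'
#' Partitions the variance of certainty-masked composite genotypes across a
#' three-level hierarchy — among transects, among elevation sites within
#' transects, within sites — using squared Euclidean distances between
#' individuals (pairwise-complete over non-missing loci, rescaled by the
#' fraction of loci compared) and the standard nested moment equations with
#' unequal-sample-size coefficients. phi-statistics:
#' `phi_CT = s2_a/s2_tot`, `phi_SC = s2_b/(s2_b + s2_c)`,
#' `phi_ST = (s2_a + s2_b)/s2_tot`. Negative components are reported as-is
#' with a flag (truncating would bias the percentages).
#'
#' Permutation p-values: `phi_ST` permutes individuals across all sites;
#' `phi_SC` permutes individuals among sites within their transect;
#' `phi_CT` permutes whole sites among transects. Each p includes the
#' observed statistic in the null set.
#'
#' @param gm A `genotype_fit` (composite genotypes).
#' @param samples Metadata tibble (`individual_id`, `site_id`, `transect_id`).
#' @param certainty_tol Certainty half-width passed to
#'   [genotype_certainty_mask()]; `NULL` disables masking.
#' @param n_perm Number of permutations per level.
#' @param seed Integer seed.
#' @return List of class `amova_result`: variance components, percentages,
#'   phi-statistics, p-values, flags.
#' @export
amova <- function(gm, samples, certainty_tol = 0.1, n_perm = 999L, seed = 1L) {
  samples <- tibble::as_tibble(samples)
  comp <- if (inherits(gm, "genotype_fit")) gm$composite else gm
  meta <- samples[match(rownames(comp), samples$individual_id), ]
  if (anyNA(meta$site_id)) stop("individuals missing from metadata")
  if (length(unique(meta$transect_id)) < 2L) stop("need >= 2 transects")
  site_tab <- table(meta$site_id)
  if (any(site_tab < 2L)) stop("every site needs >= 2 individuals")
  if (!is.null(certainty_tol)) {
    mask <- genotype_certainty_mask(comp, tol = certainty_tol)
    comp[!mask] <- NA_real_
  }
  d2 <- pairwise_sq_distances(comp)
  site <- as.factor(meta$site_id)
  transect <- as.factor(meta$transect_id)
  obs <- amova_components(d2, site, transect)
  if (sum(unlist(obs$ss[2:4])) == 0) {
    return(structure(list(degenerate = TRUE,
                          message = "all individuals identical: zero variance"),
                     class = "amova_result"))
  }
  phi <- phi_stats(obs)
  tot <- obs$sigma_a + obs$sigma_b + obs$sigma_c
  pct <- 100 * c(obs$sigma_a, obs$sigma_b, obs$sigma_c) / tot

  set.seed(seed)
  n <- nrow(d2)
  # phi_ST: permute individuals across everything
  p_st <- perm_p(n_perm, phi$phi_ST, function() {
    perm <- sample.int(n)
    phi_stats(amova_components(d2[perm, perm], site, transect))$phi_ST
  })
  # phi_SC: permute individuals among sites within transects
  by_transect <- split(seq_len(n), transect)
  p_sc <- perm_p(n_perm, phi$phi_SC, function() {
    perm <- seq_len(n)
    for (idx in by_transect) perm[idx] <- idx[sample.int(length(idx))]
    phi_stats(amova_components(d2[perm, perm], site, transect))$phi_SC
  })
  # phi_CT: permute whole sites among transects
  site_levels <- levels(site)
  p_ct <- perm_p(n_perm, phi$phi_CT, function() {
    new_transect_of_site <- sample(rep(levels(transect),
                                       each = length(site_levels) /
                                         nlevels(transect)))
    tr_perm <- factor(new_transect_of_site[match(site, site_levels)])
    phi_stats(amova_components(d2, site, tr_perm))$phi_CT
  })

  structure(list(
    degenerate = FALSE,
    sigma2 = c(among_transects = obs$sigma_a,
               among_sites_within = obs$sigma_b,
               within_sites = obs$sigma_c),
    pct = setNames(pct, c("among_transects", "among_sites_within",
                          "within_sites")),
    phi = c(phi_CT = phi$phi_CT, phi_SC = phi$phi_SC, phi_ST = phi$phi_ST),
    p = c(p_CT = p_ct, p_SC = p_sc, p_ST = p_st),
    df = obs$df,
    negative_components = any(c(obs$sigma_a, obs$sigma_b, obs$sigma_c) < 0),
    n_perm = as.integer(n_perm)),
    class = "amova_result")
}

perm_p <- function(n_perm, observed, draw) {
  exceed <- 0L
  for (b in seq_len(n_perm)) if (draw() >= observed) exceed <- exceed + 1L
  (1 + exceed) / (1 + n_perm)
}

#' @export
print.amova_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<amova_result> degenerate: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat("<amova_result>\n")
  print(tidy.amova_result(x))
  invisible(x)
}

#' Tidy an AMOVA result
#'
#' @param x An `amova_result`.
#' @param ... Unused.
#' @return Tibble with one row per stratum: variance component, percentage,
#'   phi-statistic and permutation p-value.
#' @export
tidy.amova_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    return(tibble::tibble(stratum = character(), sigma2 = numeric(),
                          pct = numeric(), phi = numeric(), p = numeric()))
  }
  tibble::tibble(
    stratum = c("among_transects", "among_sites_within_transects",
                "within_sites"),
    sigma2 = unname(x$sigma2),
    pct = unname(x$pct),
    phi = c(x$phi[["phi_CT"]], x$phi[["phi_SC"]], x$phi[["phi_ST"]]),
    phi_label = c("phi_CT", "phi_SC", "phi_ST"),
    p = c(x$p[["p_CT"]], x$p[["p_SC"]], x$p[["p_ST"]]))
}
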