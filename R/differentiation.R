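# Pairwise differentiation: Hudson-estimator F_ST (locus and genome-wide,
# ratio of averages), Nei's genetic distance, and the permutation null on
# site identity.

#' Hudson's locus-specific F_ST estimator
#'
#' Method-of-moments estimator with finite-sample corrections:
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`
#' where `n1`, `n2` are allele counts (2 x individuals). Vectorised over loci.
#' Loci monomorphic for the same allele in both samples have a zero
#' denominator and return `NA` (undefined).
#'
#' @param p1,p2 Allele frequencies in \[0, 1\] (vectors over loci).
#' @param n1,n2 Allele counts (>= 2).
#' @return Numeric vector of locus F_ST values (can be negative; `NA` where
#'   undefined).
#' @export
hudson_fst_locus <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) stop("allele counts must be >= 2")
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

# numerator/denominator components, for ratio-of-averages combination
hudson_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Genome-wide Hudson F_ST (ratio of averages)
#'
#' Combines loci as `sum(numerators) / sum(denominators)`, skipping loci with
#' zero denominator — the recommended way to average the Hudson estimator
#' (the average of per-locus ratios is biased).
#'
#' @inheritParams hudson_fst_locus
#' @return A single genome-wide F_ST value.
#' @export
hudson_fst_genomewide <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) stop("allele counts must be >= 2")
  comp <- hudson_components(p1, n1, p2, n2)
  ok <- comp$den != 0
  if (!any(ok)) stop("all loci monomorphic: genome-wide F_ST undefined")
  sum(comp$num[ok]) / sum(comp$den[ok])
}

#' Nei's standard genetic distance
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` over biallelic loci, with
#' `Jxy = mean over loci of (p1 p2 + q1 q2)`, `Jx = mean(p1^2 + q1^2)`,
#' `Jy = mean(p2^2 + q2^2)`. Returns `Inf` when the populations share no
#' alleles (`Jxy = 0`).
#'
#' @param p1,p2 Allele-frequency vectors (frequency of the same allele in the
#'   two populations).
#' @return Non-negative distance (or `Inf`).
#' @export
nei_distance <- function(p1, p2) {
  stopifnot(length(p1) == length(p2), length(p1) >= 1L)
  jxy <- mean(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- mean(p1^2 + (1 - p1)^2)
  jy <- mean(p2^2 + (1 - p2)^2)
  if (jxy == 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

# site allele frequencies from composite genotypes: p = mean(composite)/2
site_freqs_from_composite <- function(gm, samples, sites) {
  comp <- gm$composite
  lapply(setNames(sites, sites), function(s) {
    rows <- which(samples$site_id[match(rownames(comp),
                                        samples$individual_id)] == s)
    list(p = colMeans(comp[rows, , drop = FALSE]) / 2, n = 2L * length(rows))
  })
}

#' Permutation test of pairwise genome-wide F_ST
#'
#' The observed statistic is genome-wide Hudson F_ST computed from
#' composite-genotype allele frequencies (`p = mean(composite) / 2`, allele
#' count `2 x individuals`). The null shuffles the pooled individuals' site
#' labels (preserving group sizes) `n_perm` times; 95% bounds are the
#' empirical 2.5/97.5 percentiles (normal-approximation bounds are reported
#' alongside). The verdict is `greater` when the observed value exceeds the
#' upper bound, `smaller` below the lower, else `ns`.
#'
#' @param gm A `genotype_fit`.
#' @param samples Metadata tibble.
#' @param site_a,site_b Site ids.
#' @param n_perm Number of permutations (100 mirrors the original analysis).
#' @param seed Integer seed.
#' @return One-row tibble (`pairwise_result`): observed F_ST, null summary,
#'   verdict, Nei's D.
#' @export
fst_permutation_test <- function(gm, samples, site_a, site_b,
                                 n_perm = 100L, seed = 1L) {
  if (n_perm < 20L) warning("n_perm < 20: null percentiles are unstable")
  samples <- tibble::as_tibble(samples)
  comp <- gm$composite
  site_of <- samples$site_id[match(rownames(comp), samples$individual_id)]
  rows_a <- which(site_of == site_a)
  rows_b <- which(site_of == site_b)
  if (length(rows_a) < 2L || length(rows_b) < 2L) {
    stop("both sites need at least 2 individuals")
  }
  pooled <- comp[c(rows_a, rows_b), , drop = FALSE]
  na <- length(rows_a); nb <- length(rows_b)
  stat <- function(idx_a) {
    pa <- colMeans(pooled[idx_a, , drop = FALSE]) / 2
    pb <- colMeans(pooled[-idx_a, , drop = FALSE]) / 2
    hudson_fst_genomewide(pa, 2L * na, pb, 2L * nb)
  }
  observed <- stat(seq_len(na))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    stat(sample.int(na + nb, na))
  }, numeric(1))
  lo <- unname(quantile(null, 0.025))
  hi <- unname(quantile(null, 0.975))
  verdict <- if (observed > hi) "greater" else if (observed < lo) "smaller" else "ns"
  pa <- colMeans(comp[rows_a, , drop = FALSE]) / 2
  pb <- colMeans(comp[rows_b, , drop = FALSE]) / 2
  tibble::tibble(
    site_a = site_a, site_b = site_b,
    observed_fst = observed,
    null_mean = mean(null), null_sd = sd(null),
    null_lo95 = lo, null_hi95 = hi,
    null_lo95_norm = mean(null) - 1.96 * sd(null),
    null_hi95_norm = mean(null) + 1.96 * sd(null),
    verdict = verdict,
    nei_d = nei_distance(pa, pb),
    n_perm = as.integer(n_perm))
}

#' Pairwise differentiation over all site pairs
#'
#' Runs [fst_permutation_test()] for every pair of sites (15 rows for the
#' six-site design), in the same shape as a pairwise-differentiation summary
#' table: observed mean F_ST against the permutation null with 95% bounds,
#' plus Nei's D.
#'
#' @inheritParams fst_permutation_test
#' @return Tibble with one row per site pair, class `pairwise_result`.
#' @export
pairwise_differentiation <- function(gm, samples, n_perm = 100L, seed = 1L) {
  sites <- sort(unique(samples$site_id))
  pairs <- combn(sites, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    fst_permutation_test(gm, samples, pairs[1, k], pairs[2, k],
                         n_perm = n_perm, seed = seed + k)
  })
  class(out) <- c("pairwise_result", class(out))
  out
}

#' Site-by-site genetic distance matrices
#'
#' @param gm A `genotype_fit`.
#' @param samples Metadata tibble.
#' @param kind `"nei"` (Nei's D) or `"fst"` (genome-wide Hudson F_ST; may be
#'   negative).
#' @return Symmetric site-labelled matrix with zero diagonal.
#' @export
genetic_distance_matrix <- function(gm, samples, kind = c("nei", "fst")) {
  kind <- match.arg(kind)
  sites <- sort(unique(samples$site_id))
  fr <- site_freqs_from_composite(gm, tibble::as_tibble(samples), sites)
  k <- length(sites)
  m <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- if (kind == "nei") {
        nei_distance(fr[[i]]$p, fr[[j]]$p)
      } else {
        hudson_fst_genomewide(fr[[i]]$p, fr[[i]]$n, fr[[j]]$p, fr[[j]]$n)
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}
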