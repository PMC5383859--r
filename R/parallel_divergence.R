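# Parallel locus-specific divergence across replicated elevational contrasts:
# per-transect high-vs-low locus F_ST, quantile outlier sets, shared-outlier
# counts, a 10 000-permutation null, and its closed-form expectation.

#' Locus-specific F_ST for each elevational contrast
#'
#' For every transect, Hudson's locus estimator between the high- and
#' low-elevation site (frequencies from composite genotypes, allele counts
#' `2 x individuals`). Loci with a zero denominator in a contrast are `NA`
#' (undefined) in that column.
#'
#' @param gm A `genotype_fit`.
#' @param samples Metadata tibble with `site_id`, `transect_id`,
#'   `elevation_class`.
#' @return Tibble of class `contrast_fst`: `locus_id` plus one F_ST column
#'   per transect (columns ordered by transect id).
#' @export
contrast_fst <- function(gm, samples) {
  samples <- tibble::as_tibble(samples)
  comp <- gm$composite
  meta <- samples[match(rownames(comp), samples$individual_id), ]
  transects <- sort(unique(meta$transect_id))
  out <- tibble::tibble(locus_id = gm$loci$locus_id)
  for (tr in transects) {
    hi <- which(meta$transect_id == tr & meta$elevation_class == "high")
    lo <- which(meta$transect_id == tr & meta$elevation_class == "low")
    if (length(hi) < 1L || length(lo) < 1L) {
      stop("transect ", tr, " lacks a high or low site")
    }
    p_hi <- colMeans(comp[hi, , drop = FALSE]) / 2
    p_lo <- colMeans(comp[lo, , drop = FALSE]) / 2
    out[[tr]] <- hudson_fst_locus(p_hi, 2L * length(hi), p_lo, 2L * length(lo))
  }
  class(out) <- c("contrast_fst", class(out))
  out
}

#' Quantile outlier sets per contrast
#'
#' For each contrast column, the threshold is the empirical quantile of the
#' defined (non-`NA`) locus F_ST values, using linear interpolation between
#' order statistics (rank `1 + (L - 1) q`); the outlier set contains the loci
#' strictly above the threshold.
#'
#' @param tbl A `contrast_fst` tibble.
#' @param q Quantile in (0, 1), e.g. 0.99.
#' @param min_defined Minimum number of defined loci required per contrast.
#' @return Named list of character vectors of outlier locus ids, one per
#'   contrast.
#' @export
outlier_sets <- function(tbl, q, min_defined = 100L) {
  stopifnot(q > 0, q < 1)
  cols <- setdiff(names(tbl), "locus_id")
  lapply(setNames(cols, cols), function(cn) {
    x <- tbl[[cn]]
    ok <- !is.na(x)
    if (sum(ok) < min_defined) {
      stop("fewer than ", min_defined, " defined loci in contrast ", cn)
    }
    thr <- unname(quantile(x[ok], q, type = 7))
    tbl$locus_id[ok & x > thr]
  })
}

#' Count loci shared between outlier sets
#'
#' @param sets List of three locus-id sets.
#' @return Named integer vector: `exactly2` (loci in exactly two sets) and
#'   `exactly3` (loci in all three).
#' @export
count_shared <- function(sets) {
  stopifnot(length(sets) == 3L)
  cnt <- table(unlist(lapply(sets, unique)))
  c(exactly2 = sum(cnt == 2L), exactly3 = sum(cnt == 3L))
}

#' Permutation null for shared outlier counts
#'
#' Each permutation draws three independent uniform random subsets of the
#' observed set sizes from `L` loci (equivalent to permuting locus labels
#' within each contrast) and counts loci shared by exactly two and by all
#' three subsets.
#'
#' @param set_sizes Integer vector of three outlier-set sizes.
#' @param L Number of loci.
#' @param n_perm Number of permutations (10 000 mirrors the original test).
#' @param seed Integer seed.
#' @return List with means, empirical 95% CIs, standard deviations and the
#'   raw null draws for `exactly2` and `exactly3`.
#' @export
permutation_null <- function(set_sizes, L, n_perm = 10000L, seed = 1L) {
  stopifnot(length(set_sizes) == 3L, all(set_sizes <= L), all(set_sizes >= 0))
  set.seed(seed)
  e2 <- integer(n_perm); e3 <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    cnt <- tabulate(c(sample.int(L, set_sizes[1]),
                      sample.int(L, set_sizes[2]),
                      sample.int(L, set_sizes[3])), nbins = L)
    e3[b] <- sum(cnt == 3L)
    e2[b] <- sum(cnt == 2L)
  }
  list(
    expected2_mean = mean(e2), expected3_mean = mean(e3),
    expected2_lo95 = unname(quantile(e2, 0.025)),
    expected2_hi95 = unname(quantile(e2, 0.975)),
    expected3_lo95 = unname(quantile(e3, 0.025)),
    expected3_hi95 = unname(quantile(e3, 0.975)),
    expected2_sd = sd(e2), expected3_sd = sd(e3),
    draws2 = e2, draws3 = e3, n_perm = as.integer(n_perm))
}

#' Closed-form expectations for shared outlier counts
#'
#' Independent uniform subsets of sizes `m1`, `m2`, `m3` from `L` loci:
#' `E[exactly3] = m1 m2 m3 / L^2` and
#' `E[exactly2] = (m1 m2 (L - m3) + m1 m3 (L - m2) + m2 m3 (L - m1)) / L^2`.
#' Serves as the analytic oracle for [permutation_null()].
#'
#' @param m1,m2,m3 Set sizes.
#' @param L Number of loci.
#' @return Named numeric vector `c(exactly2, exactly3)`.
#' @export
analytic_expectation <- function(m1, m2, m3, L) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2); m3 <- as.numeric(m3)
  L <- as.numeric(L)
  e3 <- unname(m1 * m2 * m3 / L^2)
  e2 <- unname((m1 * m2 * (L - m3) + m1 * m3 * (L - m2) +
                  m2 * m3 * (L - m1)) / L^2)
  c(exactly2 = e2, exactly3 = e3)
}

#' Test for parallel divergence across elevational contrasts
#'
#' The full parallelism test: locus-specific F_ST per high/low contrast,
#' outlier sets above each requested quantile, observed shared counts, the
#' permutation null (restricted to loci defined in all three contrasts) and
#' the closed-form expectations.
#'
#' @param gm A `genotype_fit`.
#' @param samples Metadata tibble.
#' @param quantiles Quantiles defining outlier sets.
#' @param n_perm Permutations for the null.
#' @param seed Integer seed.
#' @return Tibble of class `parallel_divergence_result`, one row per
#'   quantile: set sizes, observed exactly-2/exactly-3 counts, null means and
#'   95% CIs, analytic expectations, and the number of loci used.
#' @export
parallel_divergence_test <- function(gm, samples,
                                     quantiles = c(0.97, 0.98, 0.99),
                                     n_perm = 10000L, seed = 1L) {
  tbl <- contrast_fst(gm, samples)
  cols <- setdiff(names(tbl), "locus_id")
  defined <- stats::complete.cases(tbl[cols])
  tbl_def <- tbl[defined, ]
  L <- nrow(tbl_def)
  out <- purrr::map_dfr(seq_along(quantiles), function(i) {
    q <- quantiles[i]
    sets <- outlier_sets(tbl_def, q)
    sizes <- lengths(sets)
    obs <- count_shared(sets)
    nul <- permutation_null(sizes, L, n_perm = n_perm, seed = seed + i)
    ana <- analytic_expectation(sizes[1], sizes[2], sizes[3], L)
    tibble::tibble(
      quantile = q,
      set_size_1 = sizes[[1]], set_size_2 = sizes[[2]], set_size_3 = sizes[[3]],
      observed_exactly2 = obs[["exactly2"]],
      observed_exactly3 = obs[["exactly3"]],
      expected2_mean = nul$expected2_mean,
      expected2_lo95 = nul$expected2_lo95,
      expected2_hi95 = nul$expected2_hi95,
      expected3_mean = nul$expected3_mean,
      expected3_lo95 = nul$expected3_lo95,
      expected3_hi95 = nul$expected3_hi95,
      analytic_expected2 = ana[["exactly2"]],
      analytic_expected3 = ana[["exactly3"]],
      n_loci = L, n_perm = as.integer(n_perm))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$quantile))
  class(out) <- c("parallel_divergence_result", class(out))
  out
}
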