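# Synthetic GBS generator: Balding-Nichols site frequencies, HWE genotypes,
# negative-binomial depths, binomial read counts -> genotype likelihoods.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: six sites arranged
#' as three transects each with one high- and one low-elevation site, weak
#' drift-based structure (Balding-Nichols F = 0.02, the genome-wide
#' differentiation regime of the real data), low GBS coverage (negative
#' binomial, mean 8x), and optionally a set of loci whose allele frequencies
#' are shifted in parallel between elevation classes in every transect.
#'
#' @param n_loci Number of biallelic loci.
#' @param samples_per_site Individuals per site (scalar or length-6 vector,
#'   site order `T1_H, T1_L, T2_H, T2_L, T3_H, T3_L`).
#' @param fst_total Balding-Nichols drift parameter F per site, in (0, 1);
#'   0 is the no-structure limit.
#' @param n_outlier_loci Number of elevation-divergent loci to spike.
#' @param outlier_delta Allele-frequency shift (+delta at high sites, -delta at
#'   low sites, clipped to \[0.01, 0.99\]).
#' @param depth_mean Mean read depth.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed, emulating uneven GBS coverage).
#' @param error_rate Symmetric per-read sequencing error rate, in (0, 0.5).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000, samples_per_site = 25, fst_total = 0.02,
                       n_outlier_loci = 0, outlier_delta = 0.3,
                       depth_mean = 8, depth_dispersion = 5,
                       error_rate = 0.01, seed = 1L) {
  if (length(samples_per_site) == 1L) samples_per_site <- rep(samples_per_site, 6L)
  stopifnot(length(samples_per_site) == 6L, n_loci >= 1L,
            n_outlier_loci <= n_loci, n_outlier_loci >= 0L,
            fst_total >= 0, fst_total < 1,
            outlier_delta > 0, outlier_delta < 1,
            depth_mean > 0, depth_dispersion > 0,
            error_rate > 0, error_rate < 0.5)
  structure(list(n_loci = as.integer(n_loci),
                 samples_per_site = as.integer(samples_per_site),
                 fst_total = fst_total,
                 n_outlier_loci = as.integer(n_outlier_loci),
                 outlier_delta = outlier_delta,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# canonical six-site design, mirroring a three-transect high/low layout
default_site_design <- function() {
  tibble::tibble(
    site_id = c("T1_H", "T1_L", "T2_H", "T2_L", "T3_H", "T3_L"),
    transect_id = rep(c("T1", "T2", "T3"), each = 2),
    elevation_class = rep(c("high", "low"), 3),
    latitude = c(39.41881, 39.44510, 39.31992, 39.35778, 38.69641, 38.54683),
    longitude = -c(120.30687, 120.21723, 119.89655, 119.85749,
                   120.00704, 120.30694),
    elevation_m = c(2428, 1952, 2590.8, 1891.59, 2535.33, 1973.58))
}

#' Simulate per-site allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each site's frequency is
#' Beta-distributed with mean p and variance F p(1-p) (shape parameters
#' `p(1-F)/F` and `(1-p)(1-F)/F`). At spiked outlier loci every transect's
#' high-elevation site is shifted by `+outlier_delta` and its low site by
#' `-outlier_delta` (clipped to \[0.01, 0.99\]), so outliers are parallel
#' across transects by construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `truth_set` with `ancestral_freqs` (L),
#'   `site_freqs` (6 x L), `outlier_locus_ids`, and the site design table.
#' @export
simulate_site_frequencies <- function(config) {
  set.seed(config$seed)
  L <- config$n_loci
  design <- default_site_design()
  p <- runif(L, 0.05, 0.95)
  F <- config$fst_total
  site_freqs <- matrix(NA_real_, 6L, L,
                       dimnames = list(design$site_id, NULL))
  if (F == 0) {
    site_freqs[] <- rep(p, each = 6L)
  } else {
    k <- (1 - F) / F
    for (s in 1:6) site_freqs[s, ] <- rbeta(L, p * k, (1 - p) * k)
  }
  outliers <- integer(0)
  if (config$n_outlier_loci > 0L) {
    outliers <- sort(sample.int(L, config$n_outlier_loci))
    hi <- which(design$elevation_class == "high")
    lo <- which(design$elevation_class == "low")
    site_freqs[hi, outliers] <- site_freqs[hi, outliers] + config$outlier_delta
    site_freqs[lo, outliers] <- site_freqs[lo, outliers] - config$outlier_delta
    site_freqs <- pmin(pmax(site_freqs, 0.01), 0.99)
  }
  structure(list(config = config, design = design, ancestral_freqs = p,
                 site_freqs = site_freqs,
                 outlier_locus_ids = paste0("L", outliers),
                 true_genotypes = NULL),
            class = "truth_set")
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's genotype at each locus is Binomial(2, p_site), matching
#' the HWE prior the genotype model assumes.
#'
#' @param truth Output of [simulate_site_frequencies()].
#' @return The `truth_set` with `true_genotypes` (N x L integer matrix),
#'   `individuals`, and a `samples` metadata tibble filled in.
#' @export
simulate_genotypes <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 1L)
  nps <- config$samples_per_site
  site_of <- rep(1:6, times = nps)
  N <- sum(nps); L <- config$n_loci
  ids <- paste0(rep(truth$design$site_id, times = nps), "_",
                unlist(lapply(nps, seq_len)))
  g <- matrix(NA_integer_, N, L, dimnames = list(ids, NULL))
  for (s in 1:6) {
    rows <- which(site_of == s)
    g[rows, ] <- rbinom(length(rows) * L, 2L,
                        rep(truth$site_freqs[s, ], each = length(rows)))
  }
  truth$individuals <- ids
  truth$true_genotypes <- g
  truth$samples <- tibble::tibble(individual_id = ids) |>
    dplyr::mutate(site_id = truth$design$site_id[site_of]) |>
    dplyr::left_join(truth$design, by = "site_id")
  truth
}

#' Simulate read depths and genotype likelihoods
#'
#' Depth is negative binomial (mean `depth_mean`, size `depth_dispersion`);
#' given depth d and true genotype g, the non-reference read count is
#' Binomial(d, mu_g) with mu_0 = error_rate, mu_1 = 0.5, mu_2 = 1 - error_rate;
#' the likelihood of each genotype is the binomial pmf of that count, stored
#' max-normalised. Zero depth yields the uninformative triple (1, 1, 1).
#'
#' @param truth Output of [simulate_genotypes()].
#' @return A [gl_matrix()] object.
#' @export
simulate_likelihoods <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 2L)
  g <- truth$true_genotypes
  N <- nrow(g); L <- ncol(g)
  eps <- config$error_rate
  mu <- c(eps, 0.5, 1 - eps)[g + 1L]
  d <- matrix(rnbinom(N * L, size = config$depth_dispersion,
                      mu = config$depth_mean), N, L)
  k <- matrix(rbinom(N * L, as.vector(d), mu), N, L)
  lik <- array(NA_real_, c(N, L, 3))
  lik[, , 1] <- dbinom(k, d, eps)
  lik[, , 2] <- dbinom(k, d, 0.5)
  lik[, , 3] <- dbinom(k, d, 1 - eps)
  loci <- tibble::tibble(
    locus_id = paste0("L", seq_len(L)),
    contig_id = paste0("ctg", seq_len(L)),
    pos = rep(50L, L),
    ref = rep("A", L), alt = rep("G", L))
  gl_matrix(truth$individuals, loci, lik, d)
}

#' Simulate a full synthetic GBS dataset
#'
#' Convenience wrapper chaining [simulate_site_frequencies()],
#' [simulate_genotypes()] and [simulate_likelihoods()].
#'
#' @param config A [sim_config()].
#' @return A list with `gl` (a [gl_matrix()]), `samples` (metadata tibble) and
#'   `truth` (the `truth_set`, for parameter-recovery checks).
#' @export
simulate_gbs <- function(config) {
  truth <- simulate_site_frequencies(config)
  truth <- simulate_genotypes(truth)
  gl <- simulate_likelihoods(truth)
  list(gl = gl, samples = truth$samples, truth = truth)
}
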