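# Hierarchical Bayesian genotype-probability model: population allele
# frequencies act as priors and are estimated jointly with genotypes by Gibbs
# sampling, so low-coverage calls are shrunk toward the group frequency.

#' MCMC settings for the genotype model
#'
#' Defaults match the analysis this package reproduces: 10 000 steps, 6 000
#' burn-in, retain every 2nd step (2 000 posterior samples).
#'
#' @param n_steps Total MCMC steps.
#' @param burn_in Burn-in steps discarded.
#' @param thin Retain every `thin`-th post-burn-in step.
#' @param seed Integer seed.
#' @param grouping `"per_site"` (allele-frequency prior estimated per site,
#'   default) or `"pooled"` (one prior across all individuals).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_steps = 10000L, burn_in = 6000L, thin = 2L,
                          seed = 1L, grouping = c("per_site", "pooled")) {
  grouping <- match.arg(grouping)
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(burn_in < n_steps, thin >= 1L)
  if ((n_steps - burn_in) / thin < 100) {
    stop("fewer than 100 retained samples; increase n_steps or reduce thin")
  }
  structure(list(n_steps = n_steps, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), grouping = grouping),
            class = "mcmc_settings")
}

#' Fit the Bayesian genotype-probability model
#'
#' Per locus and group, a Gibbs sampler alternates between (i) sampling each
#' individual's genotype with probability proportional to
#' `likelihood(data | g) * HWE(g | p)` where `HWE = ((1-p)^2, 2p(1-p), p^2)`
#' counting the non-reference allele, and (ii) sampling the group allele
#' frequency p from `Beta(1 + alt alleles, 1 + ref alleles)` (flat prior).
#' Posterior genotype probabilities are the retained-sample indicator means,
#' composite genotypes their 0-2 weighted mean, and allele frequencies the
#' retained-sample mean of p. Individuals with little or no coverage at a
#' locus are therefore pulled toward the group's Hardy-Weinberg expectation.
#'
#' @param gl A [gl_matrix()].
#' @param samples Sample metadata (see [read_metadata()]); every individual in
#'   `gl` must appear.
#' @param settings An [mcmc_settings()].
#' @return An object of class `genotype_fit` with elements `individuals`,
#'   `loci`, `composite` (N x L, in \[0, 2\]), `posterior` (N x L x 3),
#'   `allele_freqs` (groups x L), `samples`, `settings`.
#' @export
fit_genotype_model <- function(gl, samples, settings = mcmc_settings()) {
  samples <- tibble::as_tibble(samples)
  miss <- setdiff(gl$individuals, samples$individual_id)
  if (length(miss) > 0L) {
    stop("individuals missing from metadata: ", paste(head(miss, 5), collapse = ", "))
  }
  meta <- samples[match(gl$individuals, samples$individual_id), ]
  if (settings$grouping == "per_site") {
    group_names <- sort(unique(meta$site_id))
    group <- match(meta$site_id, group_names)
  } else {
    group_names <- "pooled"
    group <- rep(1L, length(gl$individuals))
  }
  if (any(tabulate(group, length(group_names)) == 0L)) {
    stop("a grouping level has no individuals")
  }
  n_ind <- length(gl$individuals); n_loc <- nrow(gl$loci)
  set.seed(settings$seed)
  res <- gibbs_genotype_model(matrix(gl$likelihoods[, , 1], n_ind, n_loc),
                              matrix(gl$likelihoods[, , 2], n_ind, n_loc),
                              matrix(gl$likelihoods[, , 3], n_ind, n_loc),
                              as.integer(group), length(group_names),
                              settings$n_steps, settings$burn_in, settings$thin)
  n <- length(gl$individuals); l <- nrow(gl$loci)
  posterior <- array(NA_real_, c(n, l, 3))
  posterior[, , 1] <- res$post0
  posterior[, , 2] <- res$post1
  posterior[, , 3] <- res$post2
  composite <- res$post1 + 2 * res$post2
  dimnames(composite) <- list(gl$individuals, gl$loci$locus_id)
  freqs <- res$freqs
  dimnames(freqs) <- list(group_names, gl$loci$locus_id)
  structure(list(individuals = gl$individuals, loci = gl$loci,
                 composite = composite, posterior = posterior,
                 allele_freqs = freqs, samples = meta, settings = settings),
            class = "genotype_fit")
}

#' Build a genotype-probability object directly from composite genotypes
#'
#' Used for analyses that start from an already-computed individuals x loci
#' composite genotype matrix (values in \[0, 2\]).
#'
#' @param composite N x L numeric matrix with individual row names.
#' @param loci Optional locus table; defaults to ids from column names.
#' @param samples Optional metadata tibble.
#' @return A `genotype_fit` (without posterior triples or allele frequencies).
#' @export
genotype_fit_from_composite <- function(composite, loci = NULL, samples = NULL) {
  stopifnot(is.matrix(composite), all(composite >= 0), all(composite <= 2))
  ids <- rownames(composite)
  if (is.null(ids)) stop("composite matrix needs individual row names")
  if (is.null(loci)) {
    lid <- colnames(composite)
    if (is.null(lid)) lid <- paste0("L", seq_len(ncol(composite)))
    loci <- tibble::tibble(locus_id = lid, contig_id = lid,
                           pos = 1L, ref = "A", alt = "G")
  }
  structure(list(individuals = ids, loci = tibble::as_tibble(loci),
                 composite = composite, posterior = NULL,
                 allele_freqs = NULL, samples = samples, settings = NULL),
            class = "genotype_fit")
}

#' @export
print.genotype_fit <- function(x, ...) {
  cat("<genotype_fit> ", length(x$individuals), " individuals x ",
      nrow(x$loci), " loci\n", sep = "")
  if (!is.null(x$allele_freqs)) {
    cat("  allele-frequency groups: ",
        paste(rownames(x$allele_freqs), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a genotype fit into a long tibble
#'
#' @param x A `genotype_fit`.
#' @param ... Unused.
#' @return Tibble with columns `individual_id`, `locus_id`, `composite` and,
#'   when available, the three posterior genotype probabilities.
#' @export
tidy.genotype_fit <- function(x, ...) {
  out <- tibble::tibble(
    individual_id = rep(x$individuals, times = nrow(x$loci)),
    locus_id = rep(x$loci$locus_id, each = length(x$individuals)),
    composite = as.vector(x$composite))
  if (!is.null(x$posterior)) {
    out$p_g0 <- as.vector(x$posterior[, , 1])
    out$p_g1 <- as.vector(x$posterior[, , 2])
    out$p_g2 <- as.vector(x$posterior[, , 3])
  }
  out
}

#' One-row summary of a genotype fit
#'
#' @param x A `genotype_fit`.
#' @param ... Unused.
#' @return Tibble with counts, mean composite and the fraction of
#'   high-certainty genotypes at the default 0.1 tolerance.
#' @export
glance.genotype_fit <- function(x, ...) {
  tibble::tibble(
    n_individuals = length(x$individuals),
    n_loci = nrow(x$loci),
    mean_composite = mean(x$composite),
    frac_high_certainty = mean(genotype_certainty_mask(x)))
}

#' High-certainty genotype mask
#'
#' An entry is retained when its composite genotype lies within `tol` of an
#' integer genotype (0, 1 or 2), boundary inclusive; all other entries are
#' treated as missing. Mirrors the practice of restricting AMOVA to genotype
#' probabilities with high certainty.
#'
#' @param gm A `genotype_fit` (or a bare composite matrix).
#' @param tol Half-width of the certainty band around 0, 1 and 2. Must be
#'   below 0.5 (bands would otherwise touch).
#' @return Logical N x L matrix: `TRUE` = retained.
#' @export
genotype_certainty_mask <- function(gm, tol = 0.1) {
  if (tol >= 0.5) stop("tol must be < 0.5: certainty bands would overlap")
  comp <- if (inherits(gm, "genotype_fit")) gm$composite else gm
  stopifnot(all(comp >= 0), all(comp <= 2))
  dist0 <- pmin(abs(comp - 0), abs(comp - 1), abs(comp - 2))
  # inclusive boundary, robust to binary representation of e.g. 1.1 - 1
  dist0 <= tol + 1e-9
}
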