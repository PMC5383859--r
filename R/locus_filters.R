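# SNP retention filters, applied to genotype-likelihood data before model
# fitting: presence/MAF -> one SNP per contig -> coverage-depth windows.

#' Filter configuration
#'
#' Defaults follow the retention rules of the GBS analysis this package
#' reproduces: a locus is kept when at least 90% of individuals have at least
#' one read, the naive minor-allele frequency is at least 5%, locus mean depth
#' lies in \[4, 15\] and individual mean depth in \[3, 10\] (all bounds
#' inclusive), and one SNP is retained per contig.
#'
#' @param min_presence Minimum fraction of individuals with depth >= 1.
#' @param min_maf Minimum naive minor-allele frequency (retain iff MAF >= this).
#' @param locus_depth_min,locus_depth_max Window for locus mean depth.
#' @param individual_depth_min,individual_depth_max Window for individual mean
#'   depth across retained loci.
#' @param one_per_contig Keep a single randomly chosen SNP per contig?
#' @param seed Seed for the per-contig random choice.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_presence = 0.90, min_maf = 0.05,
                          locus_depth_min = 4, locus_depth_max = 15,
                          individual_depth_min = 3, individual_depth_max = 10,
                          one_per_contig = TRUE, seed = 1L) {
  stopifnot(min_presence > 0, min_presence <= 1,
            min_maf >= 0, min_maf < 0.5,
            locus_depth_min < locus_depth_max,
            individual_depth_min < individual_depth_max)
  structure(list(min_presence = min_presence, min_maf = min_maf,
                 locus_depth_min = locus_depth_min,
                 locus_depth_max = locus_depth_max,
                 individual_depth_min = individual_depth_min,
                 individual_depth_max = individual_depth_max,
                 one_per_contig = isTRUE(one_per_contig),
                 seed = as.integer(seed)),
            class = "filter_config")
}

subset_gl <- function(gl, keep_ind = NULL, keep_loc = NULL) {
  if (is.null(keep_ind)) keep_ind <- seq_along(gl$individuals)
  if (is.null(keep_loc)) keep_loc <- seq_len(nrow(gl$loci))
  structure(list(individuals = gl$individuals[keep_ind],
                 loci = gl$loci[keep_loc, , drop = FALSE],
                 likelihoods = gl$likelihoods[keep_ind, keep_loc, , drop = FALSE],
                 depths = gl$depths[keep_ind, keep_loc, drop = FALSE]),
            class = "gl_matrix")
}

# likelihood-weighted expected genotype per entry (E[g] from normalised triple)
expected_genotypes <- function(gl) {
  tot <- gl$likelihoods[, , 1] + gl$likelihoods[, , 2] + gl$likelihoods[, , 3]
  (gl$likelihoods[, , 2] + 2 * gl$likelihoods[, , 3]) / tot
}

#' Presence and minor-allele-frequency filter
#'
#' Retains a locus when (i) the fraction of individuals with at least one read
#' is `>= min_presence` and (ii) the naive minor-allele frequency is
#' `>= min_maf`. The naive frequency is computed from likelihood-weighted
#' expected genotypes over the individuals with data:
#' `p = sum(E[g]) / (2 n_observed)`.
#'
#' @param gl A [gl_matrix()].
#' @param cfg A [filter_config()].
#' @return List with `gl` (filtered) and `log`, a tibble attributing each
#'   removed locus to the first rule that removed it.
#' @export
filter_presence_maf <- function(gl, cfg = filter_config()) {
  if (length(gl$individuals) == 0L || nrow(gl$loci) == 0L) {
    stop("empty genotype-likelihood matrix")
  }
  observed <- gl$depths >= 1L
  presence <- colMeans(observed)
  eg <- expected_genotypes(gl)
  n_obs <- colSums(observed)
  p <- ifelse(n_obs > 0, colSums(eg * observed) / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  fail_presence <- presence < cfg$min_presence
  fail_maf <- !fail_presence & (is.na(maf) | maf < cfg$min_maf)
  keep <- !fail_presence & !fail_maf
  log <- tibble::tibble(
    locus_id = gl$loci$locus_id[!keep],
    rule = as.character(ifelse(fail_presence[!keep], "presence", "maf")))
  list(gl = subset_gl(gl, keep_loc = which(keep)), log = log)
}

#' Retain a single random SNP per contig
#'
#' For contigs carrying multiple SNPs, one is chosen uniformly at random
#' (reproducibly under `seed`); single-SNP contigs pass through.
#'
#' @param gl A [gl_matrix()].
#' @param seed Integer seed.
#' @return The thinned [gl_matrix()].
#' @export
select_one_snp_per_contig <- function(gl, seed = 1L) {
  set.seed(seed)
  idx <- split(seq_len(nrow(gl$loci)), gl$loci$contig_id)
  keep <- sort(vapply(idx, function(v) {
    if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
  }, integer(1)))
  subset_gl(gl, keep_loc = keep)
}

#' Coverage-depth window filter
#'
#' First retains loci whose mean depth across individuals lies in the locus
#' window, then retains individuals whose mean depth across the retained loci
#' lies in the individual window (both windows inclusive).
#'
#' @param gl A [gl_matrix()].
#' @param cfg A [filter_config()].
#' @return List with `gl` (filtered), `removed_loci` and
#'   `removed_individuals` (character vectors).
#' @export
filter_depth_windows <- function(gl, cfg = filter_config()) {
  locus_depth <- colMeans(gl$depths)
  keep_loc <- locus_depth >= cfg$locus_depth_min &
    locus_depth <= cfg$locus_depth_max
  if (!any(keep_loc)) {
    stop("all loci removed by the locus depth window [",
         cfg$locus_depth_min, ", ", cfg$locus_depth_max,
         "]; locus mean depth range was [",
         format(min(locus_depth), digits = 3), ", ",
         format(max(locus_depth), digits = 3), "]")
  }
  out <- subset_gl(gl, keep_loc = which(keep_loc))
  ind_depth <- rowMeans(out$depths)
  keep_ind <- ind_depth >= cfg$individual_depth_min &
    ind_depth <= cfg$individual_depth_max
  removed_ind <- out$individuals[!keep_ind]
  out <- subset_gl(out, keep_ind = which(keep_ind))
  list(gl = out,
       removed_loci = gl$loci$locus_id[!keep_loc],
       removed_individuals = removed_ind)
}

#' Apply the full SNP filtering cascade
#'
#' Order: presence/MAF, then one SNP per contig, then depth windows — the
#' upstream-to-downstream order of the original analysis.
#'
#' @param gl A [gl_matrix()].
#' @param cfg A [filter_config()].
#' @return List with `gl` and a removal `log` tibble (`locus_id`, `rule`),
#'   plus `removed_individuals`.
#' @export
filter_loci <- function(gl, cfg = filter_config()) {
  step1 <- filter_presence_maf(gl, cfg)
  out <- step1$gl
  log <- step1$log
  if (cfg$one_per_contig) {
    before <- out$loci$locus_id
    out <- select_one_snp_per_contig(out, seed = cfg$seed)
    dropped <- setdiff(before, out$loci$locus_id)
    log <- dplyr::bind_rows(log, tibble::tibble(locus_id = dropped,
                                                rule = "one_per_contig"))
  }
  step3 <- filter_depth_windows(out, cfg)
  log <- dplyr::bind_rows(log, tibble::tibble(locus_id = step3$removed_loci,
                                              rule = "locus_depth"))
  list(gl = step3$gl, log = log,
       removed_individuals = step3$removed_individuals)
}
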