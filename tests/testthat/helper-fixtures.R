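# Shared fixtures built in code: tiny genotype-likelihood objects, metadata
# tables, and deterministic likelihood triples for known genotypes.

# metadata for the canonical 3-transect x {high, low} design with n per site
make_samples <- function(n_per_site = 2) {
  design <- tibble::tibble(
    site_id = c("T1_H", "T1_L", "T2_H", "T2_L", "T3_H", "T3_L"),
    transect_id = rep(c("T1", "T2", "T3"), each = 2),
    elevation_class = rep(c("high", "low"), 3),
    latitude = c(39.42, 39.45, 39.32, 39.36, 38.70, 38.55),
    longitude = -c(120.31, 120.22, 119.90, 119.86, 120.01, 120.31),
    elevation_m = c(2428, 1952, 2590.8, 1891.59, 2535.33, 1973.58))
  tidyr::uncount(design, n_per_site) |>
    dplyr::group_by(site_id) |>
    dplyr::mutate(individual_id = paste0(site_id, "_", dplyr::row_number()),
                  .before = 1) |>
    dplyr::ungroup()
}

# a certain likelihood triple for genotype g (0, 1, 2)
certain_triple <- function(g) {
  tr <- c(1e-12, 1e-12, 1e-12)
  tr[g + 1] <- 1
  tr
}

# gl_matrix from an integer genotype matrix, with fully certain likelihoods
gl_from_genotypes <- function(geno, depth = 8L, contig = NULL) {
  n <- nrow(geno); l <- ncol(geno)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(contig)) contig <- paste0("ctg", seq_len(l))
  lik <- array(1e-12, c(n, l, 3))
  for (g in 0:2) {
    idx <- which(geno == g, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      lik[cbind(idx, rep(g + 1L, nrow(idx)))] <- 1
    }
  }
  loci <- tibble::tibble(locus_id = paste0("L", seq_len(l)),
                         contig_id = contig, pos = seq_len(l),
                         ref = "A", alt = "G")
  dep <- matrix(depth, n, l)
  gl_matrix(ids, loci, lik, dep)
}

# genotype_fit wrapper around a numeric composite matrix with row names
fit_from_composite <- function(comp, samples) {
  genotype_fit_from_composite(comp, samples = samples)
}

# write a small VCF 4.2 with PL and DP fields; returns the path
write_test_vcf <- function(path, chrom, pos, ref, alt, pl, dp, ids) {
  # pl: list over loci of per-sample PL strings; dp: matrix loci x samples
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(j) {
    samples <- vapply(seq_along(ids), function(s) {
      paste0("./.:", pl[[j]][s], ":", dp[j, s])
    }, character(1))
    paste(c(chrom[j], pos[j], ".", ref[j], alt[j], ".", "PASS", ".",
            "GT:PL:DP", samples), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# brute-force sums of squares from genotype vectors (no distances):
# classic ANOVA identities on multivariate points
brute_ss <- function(comp, site, transect) {
  grand <- colMeans(comp)
  ss_tot <- sum(sweep(comp, 2, grand)^2)
  ss_wp <- 0
  for (s in unique(site)) {
    rows <- comp[site == s, , drop = FALSE]
    ss_wp <- ss_wp + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ss_wg <- 0
  for (g in unique(transect)) {
    rows <- comp[transect == g, , drop = FALSE]
    ss_wg <- ss_wg + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  list(total = ss_tot, among_groups = ss_tot - ss_wg,
       among_pops_within = ss_wg - ss_wp, within_pops = ss_wp)
}

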