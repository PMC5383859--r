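# End-to-end orchestration: simulate or ingest genotype likelihoods, filter,
# fit the genotype model, run every downstream statistic, write report tables
# and a reproducibility manifest.

#' Pipeline run configuration
#'
#' Defaults pin the analysis settings of the study design this package
#' reproduces: 100 permutations for pairwise F_ST nulls, 999 for
#' PERMANOVA/AMOVA/MRM, 10 000 for the parallel-divergence null, outlier
#' quantiles 97/98/99, AMOVA certainty tolerance 0.1, and MCMC
#' 10 000/6 000/thin-2. Per-stage seeds are derived deterministically from the
#' master seed so stages can be re-run independently.
#'
#' @param sim A [sim_config()] to simulate input data, or `NULL` when reading
#'   from files.
#' @param gl_path,metadata_path Input paths (used when `sim` is `NULL`).
#' @param gl_dialect Dialect for [read_genotype_likelihoods()].
#' @param filters A [filter_config()].
#' @param mcmc An [mcmc_settings()] (its seed is overridden by the derived
#'   stage seed).
#' @param n_perm_pairwise,n_perm_multivariate,n_perm_parallel Permutation
#'   counts for the three permutation engines.
#' @param quantiles Outlier quantiles for the parallel-divergence test.
#' @param certainty_tol AMOVA certainty tolerance.
#' @param n_pcs_dapc,k_max PCs retained for the discriminant step and the
#'   largest k searched.
#' @param n_pcs_cluster_search PCs fed to the k-means cluster search (kept
#'   high, as is conventional: the BIC is only informative when k-means runs
#'   in a reasonably high-dimensional score space).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), gl_path = NULL, metadata_path = NULL,
                       gl_dialect = "matrix_tsv",
                       filters = filter_config(), mcmc = mcmc_settings(),
                       n_perm_pairwise = 100L, n_perm_multivariate = 999L,
                       n_perm_parallel = 10000L,
                       quantiles = c(0.97, 0.98, 0.99),
                       certainty_tol = 0.1, n_pcs_dapc = 1L,
                       n_pcs_cluster_search = 60L, k_max = 6L,
                       seed = 1L) {
  if (is.null(sim) && (is.null(gl_path) || is.null(metadata_path))) {
    stop("provide either a sim config or gl_path + metadata_path")
  }
  structure(list(sim = sim, gl_path = gl_path, metadata_path = metadata_path,
                 gl_dialect = gl_dialect, filters = filters, mcmc = mcmc,
                 n_perm_pairwise = as.integer(n_perm_pairwise),
                 n_perm_multivariate = as.integer(n_perm_multivariate),
                 n_perm_parallel = as.integer(n_perm_parallel),
                 quantiles = quantiles, certainty_tol = certainty_tol,
                 n_pcs_dapc = as.integer(n_pcs_dapc),
                 n_pcs_cluster_search = as.integer(n_pcs_cluster_search),
                 k_max = as.integer(k_max), seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-stage seed from (master seed, stage name); stays < 2^31
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * (seq_len(nchar(stage)) * 131))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483629) + 1L
}

#' Run the full analysis pipeline
#'
#' Stage order: input (simulate or read) -> SNP filters -> Bayesian genotype
#' model -> PCA + PERMANOVA + DAPC, pairwise F_ST / Nei's D with permutation
#' nulls, hierarchical AMOVA, distance-matrix regression, and the
#' parallel-divergence test. When `out_dir` is given, report tables
#' (pairwise and parallel-divergence summaries, ordination scores, AMOVA and
#' MRM summaries) and a manifest JSON (seeds, parameters, stage timings) are
#' written there.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `chickpop_run` with every stage result.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  seed_of <- function(stage) stage_seed(config$seed, stage)

  input <- clock("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- seed_of("simulate")
      simulate_gbs(sim)
    } else {
      list(gl = read_genotype_likelihoods(config$gl_path, config$gl_dialect),
           samples = read_metadata(config$metadata_path), truth = NULL)
    }
  })
  samples <- validate_sample_table(input$samples)

  filt_cfg <- config$filters
  filt_cfg$seed <- seed_of("filters")
  filtered <- clock("filters", filter_loci(input$gl, filt_cfg))
  samples_kept <- samples[samples$individual_id %in% filtered$gl$individuals, ]

  mcmc <- config$mcmc
  mcmc$seed <- seed_of("genotype_model")
  gm <- clock("genotype_model",
              fit_genotype_model(filtered$gl, samples_kept, mcmc))

  pca <- clock("pca", pca_genotypes(gm))
  site_of <- samples_kept$site_id[match(rownames(pca$scores),
                                        samples_kept$individual_id)]
  elev_of <- samples_kept$elevation_class[match(rownames(pca$scores),
                                                samples_kept$individual_id)]
  perma_site <- clock("permanova_site",
                      permanova(pca$scores[, 1:2], site_of,
                                n_perm = config$n_perm_multivariate,
                                seed = seed_of("permanova_site")))
  perma_elev <- clock("permanova_elev",
                      permanova(pca$scores[, 1:2], elev_of,
                                n_perm = config$n_perm_multivariate,
                                seed = seed_of("permanova_elev")))
  n_pcs_search <- min(config$n_pcs_cluster_search, ncol(pca$scores))
  clusters <- clock("dapc_clusters",
                    dapc_find_clusters(pca, n_pcs = n_pcs_search,
                                       k_max = config$k_max,
                                       seed = seed_of("dapc")))
  dapc <- clock("dapc_assign", {
    if (clusters$best_k >= 2L) {
      dapc_assign(pca, clusters$cluster_labels, n_pcs = config$n_pcs_dapc)
    } else NULL
  })

  pairwise <- clock("pairwise_fst",
                    pairwise_differentiation(gm, samples_kept,
                                             n_perm = config$n_perm_pairwise,
                                             seed = seed_of("pairwise_fst")))
  amova_res <- clock("amova",
                     amova(gm, samples_kept,
                           certainty_tol = config$certainty_tol,
                           n_perm = config$n_perm_multivariate,
                           seed = seed_of("amova")))
  ibd <- clock("mrm", ibd_regression(gm, samples_kept,
                                     n_perm = config$n_perm_multivariate,
                                     seed = seed_of("mrm")))
  parallel <- clock("parallel_divergence",
                    parallel_divergence_test(gm, samples_kept,
                                             quantiles = config$quantiles,
                                             n_perm = config$n_perm_parallel,
                                             seed = seed_of("parallel")))

  result <- structure(list(
    config = config, samples = samples_kept, filter_log = filtered$log,
    removed_individuals = filtered$removed_individuals,
    genotypes = gm, pca = pca,
    permanova_site = perma_site, permanova_elevation = perma_elev,
    dapc_clusters = clusters, dapc = dapc,
    pairwise = pairwise, amova = amova_res, ibd = ibd, parallel = parallel,
    truth = input$truth, timings = timings),
    class = "chickpop_run")

  if (!is.null(out_dir)) write_run_bundle(result, out_dir)
  result
}

#' @export
print.chickpop_run <- function(x, ...) {
  cat("<chickpop_run> ", length(x$genotypes$individuals), " individuals x ",
      nrow(x$genotypes$loci), " loci after filtering\n", sep = "")
  cat("  PERMANOVA (sites): R2 = ", format(x$permanova_site$r2, digits = 3),
      ", p = ", format(x$permanova_site$p, digits = 3), "\n", sep = "")
  cat("  mean pairwise F_ST = ",
      format(mean(x$pairwise$observed_fst), digits = 3), "\n", sep = "")
  cat("  DAPC best k = ", x$dapc_clusters$best_k, "\n", sep = "")
  invisible(x)
}

#' Write the report bundle for a pipeline run
#'
#' Emits TSV tables (pairwise differentiation, parallel divergence, PCA
#' scores, AMOVA, MRM, filter log) plus `manifest.json` recording the
#' configuration, seeds, package version and stage timings.
#'
#' @param run A `chickpop_run`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_results_table(df, file.path(out_dir, name))
  w(run$pairwise, "pairwise_fst.tsv")
  w(run$parallel, "parallel_divergence.tsv")
  w(tidy(run$pca), "pca_scores.tsv")
  w(run$dapc_clusters$bic_by_k, "dapc_bic.tsv")
  if (!is.null(run$dapc)) w(tidy(run$dapc), "dapc_assignments.tsv")
  w(tidy(run$amova), "amova.tsv")
  w(dplyr::bind_rows(site = glance(run$permanova_site),
                     elevation = glance(run$permanova_elevation),
                     .id = "grouping"), "permanova.tsv")
  w(dplyr::bind_rows(mrm = tidy(run$ibd$mrm),
                     mantel_geo = tidy(run$ibd$mantel_geo),
                     mantel_elev = tidy(run$ibd$mantel_elev),
                     .id = "model"), "mrm.tsv")
  w(run$filter_log, "filter_log.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("chickpop")),
    master_seed = run$config$seed,
    n_individuals = length(run$genotypes$individuals),
    n_loci = nrow(run$genotypes$loci),
    config = manifest_config(run$config),
    timings = run$timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  cfg$filters <- unclass(cfg$filters)
  cfg$mcmc <- unclass(cfg$mcmc)
  cfg
}

#' One-row PERMANOVA summary
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return The result tibble itself (already one row).
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
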