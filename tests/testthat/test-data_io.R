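# Metadata parsing, likelihood container invariants, file-format round trips.

test_that("DMS coordinates parse to decimal degrees, west longitudes negative", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("individual_id", "site_id", "transect_id", "elevation_class",
          "latitude", "longitude", "elevation_m", sep = "\t"),
    paste("b1", "SH_H", "SH", "high",
          "39° 25′ 7.73″", "120° 18′ 24.72″",
          "2428", sep = "\t"),
    paste("b2", "SH_L", "SH", "low", "39.0", "−120.0", "1952", sep = "\t"),
    paste("b3", "MR_H", "MR", "high", "39° 0′ 0″",
          "119° 53′ 47.57″", "2590.8", sep = "\t"),
    paste("b4", "MR_L", "MR", "low", "39.35", "-119.85", "1891.59", sep = "\t")),
    tsv)
  meta <- read_metadata(tsv)
  expect_equal(meta$latitude[1], 39.41881, tolerance = 1e-6)
  expect_equal(meta$longitude[1], -120.30687, tolerance = 1e-6)
  expect_equal(meta$elevation_m[1], 2428)
  # decimal input unchanged (unicode minus accepted)
  expect_equal(meta$latitude[2], 39.0)
  expect_equal(meta$longitude[2], -120.0)
  # zero minutes/seconds
  expect_equal(meta$latitude[3], 39.0)
})

test_that("metadata validation rejects malformed designs", {
  base <- make_samples(2)
  dup <- base
  dup$individual_id[2] <- dup$individual_id[1]
  expect_error(validate_sample_table(dup), "duplicate")
  both <- base
  both$elevation_class[both$site_id == "T1_H"] <- c("high", "low")
  expect_error(validate_sample_table(both), "more than one")
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::mutate(base, latitude = "39° bad"), tsv)
  expect_error(read_metadata(tsv), "row")
})

test_that("likelihood triples are max-normalised and zero depth is uninformative", {
  lik <- array(NA_real_, c(1, 2, 3))
  lik[1, 1, ] <- c(0.2, 0.5, 0.3)   # depth 0 -> forced (1,1,1)
  lik[1, 2, ] <- c(0.1, 0.4, 0.2)   # max-normalised to (0.25, 1, 0.5)
  dep <- matrix(c(0L, 5L), 1, 2)
  loci <- tibble::tibble(locus_id = c("a", "b"), contig_id = c("c1", "c2"),
                         pos = c(1L, 1L), ref = "A", alt = "G")
  gl <- gl_matrix("i1", loci, lik, dep)
  expect_equal(gl$likelihoods[1, 1, ], c(1, 1, 1))
  expect_equal(gl$likelihoods[1, 2, ], c(0.25, 1, 0.5))
  expect_error(gl_matrix("i1", dplyr::mutate(loci, alt = "A"), lik, dep),
               "biallelic")
})

test_that("matrix_tsv round-trips likelihoods and depths exactly", {
  sim <- simulate_gbs(sim_config(n_loci = 30, samples_per_site = 2, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_genotype_likelihoods(sim$gl, path)
  back <- read_genotype_likelihoods(path, dialect = "matrix_tsv")
  expect_identical(back$individuals, sim$gl$individuals)
  expect_identical(back$depths, sim$gl$depths)
  expect_equal(back$likelihoods, sim$gl$likelihoods, tolerance = 1e-12)
  expect_equal(back$loci$contig_id, sim$gl$loci$contig_id)
})

test_that("vcf_gl and matrix_tsv encodings yield the same normalised object", {
  # two individuals, two biallelic loci plus one multiallelic (skipped)
  ids <- c("s1", "s2")
  pl <- list(c("0,30,300", "60,0,60"),
             c("0,3,30,5,7,9", "0,3,30,5,7,9"),  # 2 ALT alleles -> skipped
             c("10,0,10", "0,20,200"))
  dp <- matrix(c(10L, 8L, 5L, 5L, 0L, 7L), nrow = 3, byrow = TRUE)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("c1", "c2", "c3"), pos = c(5L, 9L, 11L),
                        ref = c("A", "C", "G"), alt = c("G", "T,A", "C"),
                        pl = pl, dp = dp, ids = ids)
  expect_message(gl <- read_genotype_likelihoods(vcf, dialect = "vcf_gl"),
                 "skipped 1")
  expect_equal(nrow(gl$loci), 2L)
  # PL (0, 30, 300) -> raw likelihoods (1, 1e-3, 1e-30)
  expect_equal(gl$likelihoods[1, 1, ], c(1, 1e-3, 1e-30))
  # zero-depth sample forced to the uninformative triple
  expect_equal(gl$likelihoods[1, 2, ], c(1, 1, 1))
  expect_equal(gl$depths[1, ], c(10L, 0L))

  # same data through matrix_tsv
  tsv <- tempfile(fileext = ".tsv")
  write_genotype_likelihoods(gl, tsv)
  back <- read_genotype_likelihoods(tsv, dialect = "matrix_tsv")
  expect_equal(back$likelihoods, gl$likelihoods, tolerance = 1e-12)
  expect_identical(back$depths, gl$depths)
})

test_that("result writer emits one row per record and header-only when empty", {
  sim <- simulate_gbs(sim_config(n_loci = 60, samples_per_site = 3, seed = 2))
  gm <- fit_from_composite(sim$truth$true_genotypes * 1.0, sim$samples)
  pw <- pairwise_differentiation(gm, sim$samples, n_perm = 20, seed = 1)
  expect_equal(nrow(pw), choose(6, 2))
  path <- tempfile(fileext = ".tsv")
  write_results_table(pw, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 15L)
  empty <- pw[0, ]
  write_results_table(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
})
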