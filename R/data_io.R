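#' chickpop: population-genomic structure across replicated elevational gradients
#'
#' Tools for low-coverage GBS population genomics: Bayesian genotype-probability
#' estimation from genotype likelihoods, SNP filtering, differentiation
#' statistics (Hudson F_ST, Nei's D) with permutation nulls, ordination
#' (PCA/DAPC) and PERMANOVA, hierarchical AMOVA, distance-matrix regression,
#' and a permutation test for parallel divergence across replicated
#' high/low-elevation contrasts.
#'
#' @useDynLib chickpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats quantile sd var rbinom rbeta runif rnbinom dbinom
#'   kmeans prcomp setNames complete.cases
#' @importFrom utils head combn
#' @keywords internal
"_PACKAGE"

# ---- sample metadata ---------------------------------------------------------

#' Read and validate a sample-metadata table
#'
#' The metadata table maps each sequenced individual to its sampling site,
#' transect (geographic replicate), elevation class and site coordinates.
#' Coordinates may be decimal degrees or DMS strings such as
#' `39° 25' 7.73"`. Because field tables routinely omit hemisphere signs,
#' longitudes are interpreted as west (negative) by default.
#'
#' @param path Path to a tab-separated file with columns `individual_id`,
#'   `site_id`, `transect_id`, `elevation_class`, `latitude`, `longitude`,
#'   `elevation_m`.
#' @param west_negative If `TRUE` (default), unsigned longitudes are stored
#'   negative (western hemisphere).
#' @return A validated tibble (one row per individual).
#' @export
read_metadata <- function(path, west_negative = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("individual_id", "site_id", "transect_id", "elevation_class",
                "latitude", "longitude", "elevation_m")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("metadata file is missing columns: ", paste(missing, collapse = ", "))
  }
  lat <- vapply(seq_len(nrow(df)), function(i) {
    parse_coordinate(df$latitude[i], row = i, negate = FALSE)
  }, numeric(1))
  lon <- vapply(seq_len(nrow(df)), function(i) {
    parse_coordinate(df$longitude[i], row = i, negate = west_negative)
  }, numeric(1))
  out <- tibble::tibble(
    individual_id = df$individual_id,
    site_id = df$site_id,
    transect_id = df$transect_id,
    elevation_class = df$elevation_class,
    latitude = lat,
    longitude = lon,
    elevation_m = as.numeric(df$elevation_m)
  )
  validate_sample_table(out)
}

#' Validate a sample table
#'
#' Checks the invariants of the sampling design: unique individuals, each site
#' in exactly one transect and one elevation class, coordinates in range.
#'
#' @param samples A data frame shaped like the output of [read_metadata()].
#' @return The input as a tibble, invisibly unchanged, or an error.
#' @export
validate_sample_table <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$individual_id) > 0L) {
    dup <- samples$individual_id[duplicated(samples$individual_id)]
    stop("duplicate individual_id: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(samples$elevation_class %in% c("high", "low"))) {
    stop("elevation_class must be 'high' or 'low'")
  }
  site_map <- dplyr::distinct(samples, .data$site_id, .data$transect_id,
                              .data$elevation_class)
  if (anyDuplicated(site_map$site_id) > 0L) {
    stop("a site maps to more than one transect or elevation class")
  }
  per_transect <- dplyr::count(site_map, .data$transect_id, .data$elevation_class)
  if (any(per_transect$n != 1L)) {
    stop("each transect must have exactly one high and one low site")
  }
  if (any(abs(samples$latitude) > 90) || any(abs(samples$longitude) > 180)) {
    stop("coordinates out of range")
  }
  samples
}

# Parse one coordinate: decimal degrees or DMS with unicode or ascii marks.
parse_coordinate <- function(x, row = NA_integer_, negate = FALSE) {
  x <- trimws(x)
  dec <- suppressWarnings(as.numeric(gsub("−", "-", x)))
  if (!is.na(dec)) return(dec)
  # DMS: degrees [minutes [seconds]] with degree/prime/quote markers
  m <- stringr::str_match(
    x,
    paste0("^([0-9]+(?:\\.[0-9]+)?)\\s*°?\\s*",
           "(?:([0-9]+(?:\\.[0-9]+)?)\\s*[′’']\\s*)?",
           "(?:([0-9]+(?:\\.[0-9]+)?)\\s*[″”\"][\\s]*)?$"))
  if (is.na(m[1, 1])) {
    stop("unparseable coordinate in row ", row, ": '", x, "'")
  }
  deg <- as.numeric(m[1, 2])
  minu <- ifelse(is.na(m[1, 3]), 0, as.numeric(m[1, 3]))
  sec <- ifelse(is.na(m[1, 4]), 0, as.numeric(m[1, 4]))
  val <- deg + minu / 60 + sec / 3600
  if (negate) -val else val
}

# ---- genotype-likelihood container ------------------------------------------

#' Construct a genotype-likelihood matrix object
#'
#' The pipeline's entry point: per individual and biallelic locus, the raw
#' likelihoods of the read data under genotypes 0, 1 and 2 (copies of the
#' non-reference allele), plus the read depth. Likelihood triples are stored
#' max-normalised (each triple scaled so its maximum is 1) since likelihoods
#' are defined only up to a constant; zero-depth triples are uninformative
#' `(1, 1, 1)`.
#'
#' @param individuals Character vector of individual ids (length N).
#' @param loci Tibble with columns `locus_id`, `contig_id`, `pos`, `ref`,
#'   `alt` (L rows).
#' @param likelihoods N x L x 3 array of non-negative likelihoods.
#' @param depths N x L matrix of non-negative integer read depths.
#' @return An object of class `gl_matrix`.
#' @export
gl_matrix <- function(individuals, loci, likelihoods, depths) {
  loci <- tibble::as_tibble(loci)
  n <- length(individuals); l <- nrow(loci)
  stopifnot(all(dim(likelihoods) == c(n, l, 3)), all(dim(depths) == c(n, l)))
  if (anyNA(likelihoods) || anyNA(depths)) stop("NA in likelihoods or depths")
  if (any(likelihoods < 0)) stop("negative likelihood")
  if (any(depths < 0)) stop("negative depth")
  depths <- matrix(as.integer(round(depths)), n, l)
  likelihoods <- array(as.numeric(likelihoods), c(n, l, 3))
  if (any(loci$ref == loci$alt)) stop("ref == alt: locus not biallelic")
  if (anyDuplicated(paste(loci$contig_id, loci$pos)) > 0L) {
    stop("duplicate (contig, position)")
  }
  lik <- normalize_triples(likelihoods)
  # zero depth => uninformative
  zero <- which(depths == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    for (c in 1:3) lik[cbind(zero, c)] <- 1
  }
  structure(list(individuals = individuals, loci = loci,
                 likelihoods = lik, depths = depths),
            class = "gl_matrix")
}

# scale each (i, l) triple so its maximum equals 1
normalize_triples <- function(lik) {
  m <- pmax(lik[, , 1], lik[, , 2], lik[, , 3])
  if (any(m == 0)) stop("all-zero likelihood triple")
  for (c in 1:3) lik[, , c] <- lik[, , c] / m
  lik
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("<gl_matrix> ", length(x$individuals), " individuals x ",
      nrow(x$loci), " loci; mean depth ",
      format(mean(x$depths), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.gl_matrix <- function(x) c(length(x$individuals), nrow(x$loci))

#' Read genotype likelihoods
#'
#' Reads either a VCF 4.x with per-sample genotype likelihoods (`GL`,
#' log10-scaled, or `PL`, phred-scaled) and per-sample depth (`DP`, falling
#' back to the sum of allelic depths `AD`, else 0), or the plain composite
#' long-format table written by [write_genotype_likelihoods()] (one row per
#' individual x locus: `individual locus contig pos ref alt depth L0 L1 L2`).
#' Both dialects yield the same container after max-normalisation.
#'
#' @param path File path.
#' @param dialect `"vcf_gl"` or `"matrix_tsv"`.
#' @return A [gl_matrix()] object. Non-biallelic VCF records are skipped with
#'   a message.
#' @export
read_genotype_likelihoods <- function(path, dialect = c("matrix_tsv", "vcf_gl")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix_tsv") read_gl_tsv(path) else read_gl_vcf(path)
}

read_gl_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(
      individual = readr::col_character(), locus = readr::col_character(),
      contig = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      depth = readr::col_integer(), L0 = readr::col_double(),
      L1 = readr::col_double(), L2 = readr::col_double()))
  individuals <- unique(df$individual)
  loci <- dplyr::distinct(df, locus_id = .data$locus, contig_id = .data$contig,
                          pos = .data$pos, ref = .data$ref, alt = .data$alt)
  n <- length(individuals); l <- nrow(loci)
  if (nrow(df) != n * l) stop("matrix_tsv is not a complete individual x locus grid")
  i <- match(df$individual, individuals)
  j <- match(df$locus, loci$locus_id)
  lik <- array(NA_real_, c(n, l, 3))
  dep <- matrix(NA_integer_, n, l)
  lik[cbind(i, j, 1L)] <- df$L0
  lik[cbind(i, j, 2L)] <- df$L1
  lik[cbind(i, j, 3L)] <- df$L2
  dep[cbind(i, j)] <- df$depth
  gl_matrix(individuals, loci, lik, dep)
}

read_gl_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L & fix[, "ALT"] != "."
  n_skip <- sum(!biallelic)
  if (n_skip > 0L) message("skipped ", n_skip, " non-biallelic VCF records")
  if (!any(biallelic)) stop("no biallelic records in VCF")

  has_gl <- "GL" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  has_pl <- "PL" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  if (!has_gl && !has_pl) stop("VCF lacks GL and PL genotype-likelihood fields")
  tag <- if (has_pl) "PL" else "GL"
  gmat <- vcfR::extract.gt(vcf, element = tag)[biallelic, , drop = FALSE]
  if (anyNA(gmat)) stop("missing ", tag, " values in VCF")
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(dp) || all(is.na(dp))) {
    ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)
    if (!is.null(ad)) {
      dp <- apply(ad, c(1, 2), function(s) {
        if (is.na(s)) return(NA_real_)
        sum(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
      })
    } else {
      dp <- matrix(0, nrow(gmat), ncol(gmat))
    }
  }
  dp <- dp[biallelic, , drop = FALSE]
  dp[is.na(dp)] <- 0

  individuals <- colnames(gmat)
  l <- nrow(gmat); n <- length(individuals)
  lik <- array(NA_real_, c(n, l, 3))
  for (j in seq_len(l)) {
    parts <- strsplit(gmat[j, ], ",", fixed = TRUE)
    vals <- matrix(as.numeric(unlist(parts)), nrow = 3)
    if (tag == "PL") {
      raw <- 10^(-vals / 10) # phred-scaled likelihoods
    } else {
      raw <- 10^vals # log10 likelihoods
    }
    lik[, j, ] <- t(raw)
  }
  fixb <- fix[biallelic, , drop = FALSE]
  loci <- tibble::tibble(
    locus_id = paste0(fixb[, "CHROM"], ":", fixb[, "POS"]),
    contig_id = fixb[, "CHROM"], pos = as.integer(fixb[, "POS"]),
    ref = fixb[, "REF"], alt = fixb[, "ALT"])
  gl_matrix(individuals, loci, lik, t(dp))
}

#' Write a genotype-likelihood matrix as a long-format TSV
#'
#' One row per individual x locus with header
#' `individual locus contig pos ref alt depth L0 L1 L2`. Round-trips through
#' [read_genotype_likelihoods()] exactly (likelihoods to full double precision).
#'
#' @param gl A [gl_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_likelihoods <- function(gl, path) {
  n <- length(gl$individuals); l <- nrow(gl$loci)
  df <- tibble::tibble(
    individual = rep(gl$individuals, times = l),
    locus = rep(gl$loci$locus_id, each = n),
    contig = rep(gl$loci$contig_id, each = n),
    pos = rep(gl$loci$pos, each = n),
    ref = rep(gl$loci$ref, each = n),
    alt = rep(gl$loci$alt, each = n),
    depth = as.vector(gl$depths),
    L0 = as.vector(gl$likelihoods[, , 1]),
    L1 = as.vector(gl$likelihoods[, , 2]),
    L2 = as.vector(gl$likelihoods[, , 3]))
  readr::write_tsv(df, path)
  invisible(path)
}

# ---- result writers ----------------------------------------------------------

#' Write result tables to tab-separated files
#'
#' Writes any of the pipeline's result tibbles (pairwise differentiation,
#' parallel divergence, AMOVA, MRM, ordination scores) as a TSV with headers.
#' An empty result writes a header-only file.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path)
  invisible(path)
}
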